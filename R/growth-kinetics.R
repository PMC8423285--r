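# Latent period, rise period and burst size from one-step growth curves.
#
# A one-step growth experiment samples free-phage titer at fixed intervals
# after synchronized infection. The curve has a baseline (latent) phase, a
# rise phase while infected cells lyse, and a plateau once lysis completes.
# Titers are treated in log10 space throughout (plaque titers are
# log-distributed), so all means of titers are geometric.

# Extraction rules for a single replicate:
#  * burst onset: the first point whose titer exceeds rise_factor times the
#    running geometric mean of all earlier points;
#  * latent period: the last sampled time before that point (reported at
#    sampling resolution, no interpolation);
#  * plateau: the maximal suffix of points whose pairwise log10 range is at
#    most plateau_tol;
#  * rise period: first plateau time minus latent time;
#  * burst size: plateau geometric mean / baseline geometric mean, the
#    baseline being all points before burst onset.
estimate_one_curve <- function(time_min, titer, rise_factor, plateau_tol) {
  n <- length(time_min)
  if (n < 4L) stop("need at least 4 time points", call. = FALSE)
  if (any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(titer)) || any(titer <= 0)) {
    stop("titers must be positive", call. = FALSE)
  }
  lg <- log10(titer)
  onset <- NA_integer_
  for (i in 2:n) {
    if (lg[i] > mean(lg[1:(i - 1L)]) + log10(rise_factor)) {
      onset <- i
      break
    }
  }
  if (is.na(onset)) stop("no burst detected", call. = FALSE)
  latent <- time_min[onset - 1L]
  baseline <- mean(lg[1:(onset - 1L)])
  s <- n
  while (s > 1L && diff(range(lg[(s - 1L):n])) <= plateau_tol) s <- s - 1L
  if (n - s + 1L < 2L) stop("no plateau", call. = FALSE)
  plateau <- mean(lg[s:n])
  list(
    latent_min = latent,
    rise_min = time_min[s] - latent,
    burst_size = 10^(plateau - baseline)
  )
}

#' @noRd
as_growth_frame <- function(x) {
  if (is.data.frame(x)) {
    if (!"replicate" %in% names(x)) x$replicate <- "rep1"
    need <- c("replicate", "time_min", "pfu_per_ml")
    if (!all(need %in% names(x))) {
      stop("growth data needs columns replicate, time_min, pfu_per_ml",
           call. = FALSE)
    }
    return(x[need])
  }
  if (is.list(x)) {
    frames <- lapply(seq_along(x), function(i) {
      d <- as_growth_frame(x[[i]])
      if (identical(unique(d$replicate), "rep1")) {
        d$replicate <- names(x)[i] %||% sprintf("rep%d", i)
      }
      d
    })
    return(do.call(rbind, frames))
  }
  stop("cannot interpret growth-curve input", call. = FALSE)
}

#' Estimate one-step growth kinetics
#'
#' Extracts latent period, rise period and burst size from one or more
#' replicate growth curves; see the extraction rules in the package
#' vignette. Latent and rise are reported at the sampling resolution (the
#' median across replicates), burst size as the arithmetic mean of
#' per-replicate burst sizes with its standard error.
#'
#' @param curves long-format data frame with columns `replicate`,
#'   `time_min`, `pfu_per_ml` (the `replicate` column may be omitted for a
#'   single curve), or a list of per-replicate data frames.
#' @param rise_factor titer multiple of the running baseline that marks
#'   burst onset (default 2: a doubling).
#' @param plateau_tol maximal pairwise log10 spread within the plateau
#'   (default 0.1).
#' @return A `kinetics_estimate`: list with `latent_min`, `rise_min`,
#'   `burst_size`, `burst_se` (NA for a single replicate), `n_replicates`
#'   and a `per_replicate` data frame.
#' @export
#' @examples
#' curve <- data.frame(
#'   time_min = seq(0, 60, 10),
#'   pfu_per_ml = c(1e4, 1e4, 1e4, 4e4, 1.2e5, 1.2e5, 1.2e5)
#' )
#' estimate_kinetics(curve)
estimate_kinetics <- function(curves, rise_factor = 2, plateau_tol = 0.1) {
  stopifnot(rise_factor > 1, plateau_tol > 0)
  df <- as_growth_frame(curves)
  reps <- split(df, factor(df$replicate, levels = unique(df$replicate)))
  per <- lapply(reps, function(d) {
    d <- d[order(d$time_min), ]
    tryCatch(
      as.data.frame(estimate_one_curve(d$time_min, d$pfu_per_ml,
                                       rise_factor, plateau_tol)),
      error = function(e) e
    )
  })
  failed <- vapply(per, inherits, logical(1), "error")
  if (all(failed)) stop(conditionMessage(per[[1L]]), call. = FALSE)
  if (any(failed)) {
    warning("replicate(s) dropped: ",
            paste(sprintf("%s (%s)", names(per)[failed],
                          vapply(per[failed], conditionMessage, "")),
                  collapse = "; "), call. = FALSE)
  }
  ok <- do.call(rbind, per[!failed])
  ok <- cbind(replicate = names(per)[!failed], ok)
  rownames(ok) <- NULL
  n <- nrow(ok)
  structure(
    list(
      latent_min = stats::median(ok$latent_min),
      rise_min = stats::median(ok$rise_min),
      burst_size = mean(ok$burst_size),
      burst_se = if (n > 1L) stats::sd(ok$burst_size) / sqrt(n) else NA_real_,
      n_replicates = n,
      per_replicate = ok
    ),
    class = "kinetics_estimate"
  )
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("<kinetics_estimate> latent %g min, rise %g min, ",
           "burst size %.3g%s PFU/infected cell (%d replicate%s)\n"),
    x$latent_min, x$rise_min, x$burst_size,
    if (is.na(x$burst_se)) "" else sprintf(" ± %.2g", x$burst_se),
    x$n_replicates, if (x$n_replicates == 1L) "" else "s"
  ))
  invisible(x)
}

#' Multiplicity of infection
#'
#' @param phage_added phage particles added (PFU), non-negative.
#' @param cells bacterial cells (CFU), positive.
#' @return The ratio `phage_added / cells`.
#' @export
#' @examples
#' moi(1e6, 1e6)
moi <- function(phage_added, cells) {
  stopifnot(is.numeric(phage_added), is.numeric(cells))
  if (any(phage_added < 0)) stop("phage_added must be non-negative", call. = FALSE)
  if (any(cells <= 0)) stop("cells must be positive", call. = FALSE)
  phage_added / cells
}

#' Read a one-step growth table
#'
#' Long-format TSV with columns `replicate`, `time_min`, `pfu_per_ml`.
#'
#' @param path input file path.
#' @return Data frame suitable for [estimate_kinetics()].
#' @export
read_growth_tsv <- function(path) {
  if (!file.exists(path)) stop("growth table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicate", "time_min", "pfu_per_ml")
  if (nrow(df) == 0L || !all(need %in% names(df))) {
    stop("growth table needs columns replicate, time_min, pfu_per_ml",
         call. = FALSE)
  }
  t_num <- suppressWarnings(as.numeric(df$time_min))
  y_num <- suppressWarnings(as.numeric(df$pfu_per_ml))
  bad <- which(!is.finite(t_num) | !is.finite(y_num) | y_num <= 0)
  if (length(bad)) {
    stop("malformed growth rows at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df$time_min <- t_num
  df$pfu_per_ml <- y_num
  df[need]
}
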