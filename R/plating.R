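# Titers from spot dilution series and efficiency of plating (EOP) across
# host strains. EOP expresses a phage's titer on each strain as a
# percentage of its titer on the strain it lyses most efficiently.

#' Construct a spot dilution series
#'
#' A 10-fold serial dilution spotted on a bacterial lawn: plaque counts per
#' spot, indexed by the dilution exponent (10^-exponent of the stock).
#'
#' @param dilution_exponents strictly increasing integer vector of 10-fold
#'   dilution steps.
#' @param plaque_counts non-negative integer plaque counts, one per spot.
#' @param spot_volume spotted volume in mL (default 0.01, i.e. 10 uL).
#' @return A `spot_series` object.
#' @export
spot_series <- function(dilution_exponents, plaque_counts, spot_volume = 0.01) {
  stopifnot(
    length(dilution_exponents) == length(plaque_counts),
    length(dilution_exponents) >= 1L,
    spot_volume > 0
  )
  if (any(diff(dilution_exponents) <= 0)) {
    stop("dilution exponents must be strictly increasing", call. = FALSE)
  }
  if (any(plaque_counts < 0) || any(plaque_counts != round(plaque_counts))) {
    stop("plaque counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(dilution_exponents = as.integer(dilution_exponents),
         plaque_counts = as.integer(round(plaque_counts)),
         spot_volume = spot_volume),
    class = "spot_series"
  )
}

#' @export
print.spot_series <- function(x, ...) {
  cat(sprintf("<spot_series> %d spots of %g mL; counts: %s\n",
              length(x$plaque_counts), x$spot_volume,
              paste(sprintf("1e-%d:%d", x$dilution_exponents,
                            x$plaque_counts), collapse = " ")))
  invisible(x)
}

#' Titer from a spot dilution series
#'
#' Uses the most dilute spot whose plaque count lies in the countable range
#' (minimizing plaque-overlap bias):
#' `titer = count / spot_volume * 10^exponent` in PFU/mL.
#'
#' @param series a [spot_series()].
#' @param countable_min,countable_max countable range of plaques per spot
#'   (defaults 3 and 100).
#' @return Titer in PFU/mL.
#' @export
#' @examples
#' titer_from_spots(spot_series(6, 12))
titer_from_spots <- function(series, countable_min = 3, countable_max = 100) {
  stopifnot(inherits(series, "spot_series"),
            countable_min >= 1, countable_max > countable_min)
  ok <- series$plaque_counts >= countable_min &
    series$plaque_counts <= countable_max
  if (!any(ok)) stop("series uncountable", call. = FALSE)
  i <- which(ok)[which.max(series$dilution_exponents[ok])]
  series$plaque_counts[i] / series$spot_volume *
    10^series$dilution_exponents[i]
}

#' Efficiency of plating across host strains
#'
#' EOP of each strain is its titer divided by the maximal titer over all
#' strains, times 100. The strain with the maximal titer is the reference
#' (EOP exactly 100); titer ties are broken by input order.
#'
#' @param titers named numeric vector of PFU/mL, or a data frame with
#'   columns `strain_id` (or `strain`) and `titer` (or `pfu_per_ml`).
#' @return An `eop_table` data frame with columns `strain_id`, `titer`,
#'   `eop_percent` and attribute `reference_strain`.
#' @export
#' @examples
#' efficiency_of_plating(c(KLEB011 = 1.0e9, KLEB014 = 3.2e7, KLEB015 = 4.8e6))
efficiency_of_plating <- function(titers) {
  if (is.data.frame(titers)) {
    strain <- titers[["strain_id"]] %||% titers[["strain"]]
    titer <- titers[["titer"]] %||% titers[["pfu_per_ml"]]
    if (is.null(strain) || is.null(titer)) {
      stop("titer table needs columns strain_id and titer", call. = FALSE)
    }
  } else {
    if (is.null(names(titers))) stop("titers must be named by strain", call. = FALSE)
    strain <- names(titers)
    titer <- unname(titers)
  }
  titer <- as.numeric(titer)
  if (any(!is.finite(titer)) || any(titer < 0)) {
    stop("titers must be finite and non-negative", call. = FALSE)
  }
  if (all(titer == 0)) stop("all titers are zero", call. = FALSE)
  ref_idx <- which.max(titer)  # first maximum = input-order tie break
  out <- data.frame(
    strain_id = strain,
    titer = titer,
    eop_percent = 100 * titer / titer[ref_idx],
    stringsAsFactors = FALSE
  )
  attr(out, "reference_strain") <- strain[ref_idx]
  class(out) <- c("eop_table", "data.frame")
  out
}

#' @export
print.eop_table <- function(x, ...) {
  cat(sprintf("<eop_table> reference strain: %s\n",
              attr(x, "reference_strain")))
  shown <- as.data.frame(x)
  shown$eop_percent <- signif(shown$eop_percent, 2)
  print(shown)
  invisible(x)
}

#' Read a per-strain spot-count table and compute titers
#'
#' TSV with columns `strain`, `dilution_exponent`, `plaque_count`; one titer
#' is computed per strain via [titer_from_spots()].
#'
#' @param path input file path.
#' @param countable_min,countable_max passed to [titer_from_spots()].
#' @param spot_volume spotted volume in mL.
#' @return Named numeric vector of titers (PFU/mL) in strain input order.
#' @export
read_spot_titers_tsv <- function(path, countable_min = 3, countable_max = 100,
                                 spot_volume = 0.01) {
  if (!file.exists(path)) stop("spot table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "dilution_exponent", "plaque_count")
  if (nrow(df) == 0L || !all(need %in% names(df))) {
    stop("spot table needs columns strain, dilution_exponent, plaque_count",
         call. = FALSE)
  }
  strains <- unique(df$strain)
  vapply(strains, function(s) {
    d <- df[df$strain == s, ]
    d <- d[order(d$dilution_exponent), ]
    titer_from_spots(
      spot_series(d$dilution_exponent, d$plaque_count, spot_volume),
      countable_min, countable_max
    )
  }, numeric(1))
}

#' Read a per-strain titer table
#'
#' TSV with columns `strain` and `pfu_per_ml`.
#'
#' @param path input file path.
#' @return Named numeric vector of titers in input order.
#' @export
read_titers_tsv <- function(path) {
  if (!file.exists(path)) stop("titer table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "pfu_per_ml")
  if (nrow(df) == 0L || !all(need %in% names(df))) {
    stop("titer table needs columns strain, pfu_per_ml", call. = FALSE)
  }
  stats::setNames(as.numeric(df$pfu_per_ml), df$strain)
}
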