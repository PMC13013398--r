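#' Posterior mean reaction-norm slopes of sires
#'
#' Extracts the posterior mean slope of every sire with at least
#' `min_progeny` phenotyped progeny among the supplied records.
#'
#' @param fit an [rn_fit][fit_reaction_norm()].
#' @param records the phenotype records the fit was run on (used to count
#'   progeny per sire; unknown sires, coded 0, are skipped).
#' @param min_progeny minimum progeny records per sire (default 3).
#' @return data frame (sire, n_progeny, mean_slope).
#' @export
sire_slopes <- function(fit, records, min_progeny = 3) {
  stopifnot(inherits(fit, "rn_fit"))
  known <- !(records$sire %in% c(0, "0", NA))
  cnt <- table(records$sire[known])
  keep <- names(cnt)[cnt >= min_progeny]
  keep <- keep[keep %in% colnames(fit$b)]
  if (length(keep) == 0) stop("no sires with ", min_progeny,
                              " or more progeny records")
  data.frame(sire = keep,
             n_progeny = as.integer(cnt[keep]),
             mean_slope = colMeans(fit$b[, keep, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify sires by environmental sensitivity
#'
#' Measures each sire's deviation from the reference centre of the
#' posterior mean slopes in units of the between-sire standard deviation
#' (denominator n-1) and assigns: Extremely Robust (ER, within 1 SD),
#' Robust (R, above 1 and below 2 SD), Plastic (P, at least 2 and below
#' 3 SD), Extremely Plastic (EP, at least 3 SD). The boundary at exactly
#' 1 SD is ER; exactly 2 is P; exactly 3 is EP.
#'
#' @param slopes named numeric vector of posterior mean slopes, or the
#'   data frame from [sire_slopes()].
#' @param progeny_counts optional named progeny counts; sires below
#'   `min_progeny` are dropped before the reference centre/scale are
#'   computed.
#' @param min_progeny minimum progeny per sire when `progeny_counts` is
#'   given.
#' @param center `"mean"` (deviation from the mean of sire slopes, the
#'   default: invariant to the environmental-scale origin) or `"zero"`.
#' @return data frame (sire, n_progeny, mean_slope, slope_sd_units, class)
#'   with `class` a factor with levels ER, R, P, EP. If all slopes are
#'   identical the scale is degenerate: every sire is ER and a warning is
#'   raised.
#' @export
classify_sires <- function(slopes, progeny_counts = NULL, min_progeny = 3,
                           center = c("mean", "zero")) {
  center <- match.arg(center)
  if (is.data.frame(slopes)) {
    df <- data.frame(sire = as.character(slopes$sire),
                     n_progeny = if ("n_progeny" %in% names(slopes))
                       slopes$n_progeny else NA_integer_,
                     mean_slope = slopes$mean_slope,
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(names(slopes))) names(slopes) <- seq_along(slopes)
    df <- data.frame(sire = names(slopes), n_progeny = NA_integer_,
                     mean_slope = unname(slopes), stringsAsFactors = FALSE)
  }
  if (!is.null(progeny_counts)) {
    df$n_progeny <- as.integer(progeny_counts[df$sire])
    df <- df[!is.na(df$n_progeny) & df$n_progeny >= min_progeny, ,
             drop = FALSE]
  }
  if (nrow(df) < 2) stop("need at least 2 sires to classify")
  ref <- if (center == "mean") mean(df$mean_slope) else 0
  scl <- sd(df$mean_slope)
  if (scl == 0) {
    warning("all sire slopes identical: degenerate scale, every sire ER")
    df$slope_sd_units <- 0
  } else {
    df$slope_sd_units <- abs(df$mean_slope - ref) / scl
  }
  su <- df$slope_sd_units
  cls <- ifelse(su <= 1, "ER", ifelse(su < 2, "R", ifelse(su < 3, "P", "EP")))
  df$class <- factor(cls, levels = c("ER", "R", "P", "EP"))
  rownames(df) <- NULL
  df
}

#' Class percentages
#'
#' @param classifications output of [classify_sires()].
#' @return named numeric vector of percentages over the four classes
#'   (zero-count classes reported as 0; sums to 100).
#' @export
class_percentages <- function(classifications) {
  if (nrow(classifications) == 0) stop("empty classification list")
  tab <- table(classifications$class)
  setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}
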