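#' Read a phenotype file
#'
#' Expects a delimited file with header columns `animal`, `sire`, `dam`,
#' `cg`, `cow_age`, `value`. Rows with non-numeric or non-positive
#' `cow_age`, or a non-numeric `value`, are rejected individually and
#' reported with their line numbers; a missing column is a hard error.
#'
#' @param path phenotype file.
#' @param sep field separator, default tab.
#' @return data frame of clean records; rejected rows are attached as the
#'   `"rejected"` attribute (data frame with `line` and `reason`).
#' @export
read_phenotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("animal", "sire", "dam", "cg", "cow_age", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("phenotype file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df <- df[need]
  if (nrow(df) == 0) {
    out <- data.frame(animal = character(0), sire = character(0),
                      dam = character(0), cg = character(0),
                      cow_age = numeric(0), value = numeric(0))
    attr(out, "rejected") <- data.frame(line = integer(0),
                                        reason = character(0))
    return(out)
  }
  age <- suppressWarnings(as.numeric(df$cow_age))
  val <- suppressWarnings(as.numeric(df$value))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(val)] <- "non-numeric value"
  reason[is.na(age) | !is.finite(age) | age <= 0] <- "invalid cow_age"
  reason[is.na(df$cg) | df$cg == ""] <- "empty cg"
  bad <- !is.na(reason)
  out <- df[!bad, , drop = FALSE]
  out$cow_age <- age[!bad]
  out$value <- val[!bad]
  rownames(out) <- NULL
  # line numbers count the header as line 1
  attr(out, "rejected") <- data.frame(line = which(bad) + 1L,
                                      reason = reason[bad],
                                      stringsAsFactors = FALSE)
  out
}

#' Apply contemporary-group and sire-progeny editing rules
#'
#' Retains only contemporary groups with at least `min_cg_size` records and
#' known sires with at least `min_progeny` retained progeny records. The
#' defaults encode "more than 4 individuals" per group (size >= 5) and
#' "at least 3 progeny" per sire. The two rules interact — dropping a group
#' can demote a sire and removing a sire's progeny can shrink a group — so
#' filtering is iterated to a fixed point. Records whose sire is unknown
#' are exempt from the progeny rule.
#'
#' @param records phenotype data frame (see [read_phenotypes()]).
#' @param min_cg_size minimum records per contemporary group (default 5).
#' @param min_progeny minimum retained progeny per known sire (default 3).
#' @return list with `records` (the retained subset, unmodified rows) and
#'   `report` (n_input, n_retained, n_dropped_cg, n_dropped_sire, n_passes).
#' @export
apply_edits <- function(records, min_cg_size = 5, min_progeny = 3) {
  stopifnot(min_cg_size >= 1, min_progeny >= 1)
  keep <- rep(TRUE, nrow(records))
  dropped_cg <- dropped_sire <- 0L
  passes <- 0L
  repeat {
    passes <- passes + 1L
    changed <- FALSE
    cg_n <- table(records$cg[keep])
    bad_cg <- keep & records$cg %in% names(cg_n)[cg_n < min_cg_size]
    if (any(bad_cg)) {
      dropped_cg <- dropped_cg + sum(bad_cg)
      keep[bad_cg] <- FALSE
      changed <- TRUE
    }
    known <- keep & records$sire != 0 & records$sire != "0"
    sire_n <- table(records$sire[known])
    bad_sire <- known & records$sire %in% names(sire_n)[sire_n < min_progeny]
    if (any(bad_sire)) {
      dropped_sire <- dropped_sire + sum(bad_sire)
      keep[bad_sire] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = list(n_input = nrow(records), n_retained = nrow(out),
                     n_dropped_cg = dropped_cg,
                     n_dropped_sire = dropped_sire,
                     n_passes = passes))
}
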