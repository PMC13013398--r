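#' Validate and normalise a pedigree
#'
#' A pedigree is a data frame with columns `animal`, `sire`, `dam` in which
#' unknown parents are coded `0` (or `NA`, which is recoded to `0`). Animals
#' must be topologically ordered: every known parent appears as an animal in
#' an earlier row. Unknown parents are treated as unrelated, non-inbred
#' founders from a single base population.
#'
#' @param ped data frame with columns `animal`, `sire`, `dam`.
#' @return the pedigree with ids normalised, invisibly checked.
#' @export
as_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  need <- c("animal", "sire", "dam")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  }
  ped$sire[is.na(ped$sire)] <- 0
  ped$dam[is.na(ped$dam)] <- 0
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal ids in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)])[1:3], collapse = ", "))
  }
  if (any(ped$animal == 0)) stop("animal id 0 is reserved for unknown parents")
  if (any(ped$sire == ped$animal) || any(ped$dam == ped$animal)) {
    stop("animal listed as its own parent")
  }
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- p != 0
    idx <- match(p[known], ped$animal)
    if (anyNA(idx)) {
      stop("pedigree ", col, " id(s) not present as animals: ",
           paste(unique(p[known][is.na(idx)])[1:3], collapse = ", "))
    }
    bad <- idx >= which(known)
    if (any(bad)) {
      stop("pedigree not topologically ordered: ", col, " of animal ",
           ped$animal[known][bad][1], " appears at or after its offspring")
    }
  }
  ped[need]
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes F for every animal by accumulating gene-flow contributions of
#' each ancestor's Mendelian-sampling variance. Founders (and animals with
#' at least one unknown parent) get F = 0; otherwise F equals half the
#' additive relationship between the parents.
#'
#' @param ped pedigree accepted by [as_pedigree()].
#' @return named numeric vector of inbreeding coefficients in `[0, 1)`.
#' @export
compute_inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  f <- inbreeding_cpp(s, d)
  names(f) <- ped$animal
  f
}

# Mendelian-sampling variance share d_i given parent indices and inbreeding.
# Unknown parents carry F = -1 so that d = 1 (both unknown), 0.75 - F_p/4
# (one known) and 0.5 - (F_s + F_d)/4 (both known).
mendelian_d <- function(s, d, f) {
  fs <- ifelse(s > 0, f[pmax(s, 1)], -1)
  fd <- ifelse(d > 0, f[pmax(d, 1)], -1)
  0.5 - 0.25 * (fs + fd)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with the inbreeding-adjusted Mendelian-sampling
#' variance: each animal contributes 1/d_i to its own diagonal, -1/(2 d_i)
#' to animal-parent entries and 1/(4 d_i) to parent-parent entries, where
#' d_i = 0.5 - 0.25 (F_s + F_d) (terms for unknown parents drop out and
#' d is enlarged accordingly).
#'
#' @param ped pedigree accepted by [as_pedigree()].
#' @param inbreeding optional precomputed result of [compute_inbreeding()].
#' @return sparse symmetric matrix (class `dsCMatrix`) with dimnames the
#'   animal ids, in pedigree order.
#' @export
build_a_inverse <- function(ped, inbreeding = NULL) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  if (is.null(inbreeding)) {
    inbreeding <- compute_inbreeding(ped)
  } else {
    if (!all(ped$animal %in% names(inbreeding))) {
      stop("inbreeding vector does not cover all pedigree animals")
    }
    inbreeding <- inbreeding[as.character(ped$animal)]
  }
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  alpha <- 1 / mendelian_d(s, d, as.numeric(inbreeding))

  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  i <- seq_len(n)
  add(i, i, alpha)
  for (p in list(s, d)) {
    k <- p > 0
    add(i[k], p[k], -alpha[k] / 2)
    add(p[k], i[k], -alpha[k] / 2)
    add(p[k], p[k], alpha[k] / 4)
  }
  both <- s > 0 & d > 0
  add(s[both], d[both], alpha[both] / 4)
  add(d[both], s[both], alpha[both] / 4)

  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(m)
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Intended for small pedigrees (oracles, founder bases); memory grows as
#' n^2.
#'
#' @param ped pedigree accepted by [as_pedigree()].
#' @return dense symmetric matrix A with `1 + F` on the diagonal.
#' @export
relationship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0 && d[i] > 0) A[s[i], d[i]] else 0
    A[i, i] <- 1 + asd / 2
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- numeric(i - 1)
      if (s[i] > 0) aij <- aij + A[j, s[i]] / 2
      if (d[i] > 0) aij <- aij + A[j, d[i]] / 2
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}

#' Read a pedigree from a 3-column delimited file
#'
#' @param path file with columns animal, sire, dam (header optional ids must
#'   be numeric or strings; unknown parents coded 0).
#' @param header does the file carry a header line?
#' @param sep field separator, default tab.
#' @return pedigree data frame validated by [as_pedigree()].
#' @export
read_pedigree <- function(path, header = TRUE, sep = "\t") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.delim(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (!header) names(df)[1:3] <- c("animal", "sire", "dam")
  as_pedigree(df)
}
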