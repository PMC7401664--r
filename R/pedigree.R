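#' Create a pedigree table
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` (0 = unknown
#' parent), and optionally `sex` (1 = male, 2 = female) and `birth_year`.
#' Animals must be topologically sorted (parents precede offspring); ids are
#' consecutive integers 1..n in storage order.
#'
#' @param sire,dam integer parent ids (0 = unknown).
#' @param sex,birth_year optional sidecar columns.
#' @return Object of class `pedigree` (a data frame).
#' @export
pedigree <- function(sire, dam, sex = NULL, birth_year = NULL) {
  n <- length(sire)
  stopifnot(length(dam) == n)
  sire <- as.integer(sire); dam <- as.integer(dam)
  id <- seq_len(n)
  if (any(sire >= id & sire > 0) || any(dam >= id & dam > 0))
    stop("parents must precede offspring (topological order)")
  ped <- data.frame(id = id, sire = sire, dam = dam)
  ped$sex <- if (is.null(sex)) NA_integer_ else as.integer(sex)
  ped$birth_year <- if (is.null(birth_year)) NA_integer_
                    else as.integer(birth_year)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Truncate a pedigree to a maximum ancestral depth
#'
#' Returns the sub-pedigree containing the anchor animals and all their
#' ancestors within `depth` generations; ancestors at the cut become
#' founders (parents set to unknown). Ids are relabelled consecutively; the
#' mapping to the original ids is returned as attribute `orig_id`.
#'
#' @param ped a [pedigree()].
#' @param anchor_ids animals whose ancestry is kept.
#' @param depth number of ancestral generations to retain (>= 1).
#' @return Truncated `pedigree` with attribute `orig_id`.
#' @export
truncate_pedigree <- function(ped, anchor_ids, depth = 7L) {
  if (depth < 1) stop("depth must be >= 1")
  anchor_ids <- as.integer(anchor_ids)
  if (any(anchor_ids < 1 | anchor_ids > nrow(ped)))
    stop("unknown anchor id")
  keep <- rep(FALSE, nrow(ped))
  level <- anchor_ids
  keep[level] <- TRUE
  for (g in seq_len(depth)) {
    par <- c(ped$sire[level], ped$dam[level])
    level <- unique(par[par > 0 & !keep[pmax(par, 1L)]])
    if (length(level) == 0) break
    keep[level] <- TRUE
  }
  last <- if (length(level) > 0) level else integer(0)
  orig <- which(keep)
  newid <- integer(nrow(ped))
  newid[orig] <- seq_along(orig)
  remap <- function(p, drop_parents) {
    out <- ifelse(p > 0 & keep[pmax(p, 1L)], newid[pmax(p, 1L)], 0L)
    out[drop_parents] <- 0L
    as.integer(out)
  }
  at_cut <- rep(FALSE, nrow(ped)); at_cut[last] <- TRUE
  sub <- pedigree(remap(ped$sire[orig], at_cut[orig]),
                  remap(ped$dam[orig], at_cut[orig]),
                  ped$sex[orig], ped$birth_year[orig])
  attr(sub, "orig_id") <- orig
  sub
}

#' Inverse numerator relationship matrix
#'
#' Henderson's rules with inbreeding coefficients from the Meuwissen-Luo
#' algorithm; equals the exact inverse of the tabular-method A. Unknown
#' parents are treated as unrelated non-inbred founders.
#'
#' @param ped a [pedigree()].
#' @return Sparse symmetric matrix (`Matrix::dgCMatrix`) with attribute
#'   `F` (inbreeding coefficients).
#' @export
a_inverse <- function(ped) {
  n <- nrow(ped)
  upd <- cpp_ainv_update(ped$sire, ped$dam, numeric(n), 1L)
  M <- Matrix::sparseMatrix(i = upd$i, j = upd$j, x = upd$x, dims = c(n, n))
  attr(M, "F") <- upd$F
  M
}

#' Inbreeding coefficients
#' @param ped a [pedigree()].
#' @return Numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  cpp_ainv_update(ped$sire, ped$dam, numeric(nrow(ped)), 1L)$F
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense recursive computation; quadratic in pedigree size and intended for
#' moderate pedigrees (kinship queries, cross-checks, exports).
#'
#' @param ped a [pedigree()].
#' @return Dense numeric matrix A.
#' @export
relationship_matrix <- function(ped) {
  cpp_tabular_a(ped$sire, ped$dam)
}

#' Mean kinship of a cohort
#'
#' Mean over all ordered pairs (by default including self-pairs) of the
#' kinship matrix Phi = A/2 restricted to the cohort. Only the ancestry of
#' the cohort is evaluated.
#'
#' @param ped a [pedigree()].
#' @param cohort_ids animals forming the cohort.
#' @param include_self include self-kinship pairs (default TRUE).
#' @return Mean kinship (unitless).
#' @export
mean_kinship <- function(ped, cohort_ids, include_self = TRUE) {
  cohort_ids <- as.integer(cohort_ids)
  if (length(cohort_ids) == 0) stop("empty cohort")
  sub <- truncate_pedigree(ped, cohort_ids, depth = nrow(ped))
  A <- relationship_matrix(sub)
  pos <- match(cohort_ids, attr(sub, "orig_id"))
  Ac <- A[pos, pos, drop = FALSE] / 2
  k <- length(pos)
  if (include_self) mean(Ac)
  else if (k == 1) stop("cohort of one has no non-self pairs")
  else (sum(Ac) - sum(diag(Ac))) / (k * (k - 1))
}

#' Read / write pedigree text files
#'
#' Three-column text format (id, sire, dam; 0 = unknown) with sex and
#' birth-year sidecar columns.
#'
#' @param ped a [pedigree()].
#' @param file path.
#' @return `write_pedigree` the path invisibly; `read_pedigree` a
#'   [pedigree()].
#' @export
write_pedigree <- function(ped, file) {
  write.table(as.data.frame(ped), file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t")
  pedigree(d$sire, d$dam, d$sex, d$birth_year)
}
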