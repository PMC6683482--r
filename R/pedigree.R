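#' Build a validated, topologically sorted pedigree
#'
#' @param records a data frame with columns `id`, `sire`, `dam`, `sex`
#'   (`"M"`/`"F"`) and `role` (`"ancestor"`/`"candidate"`). Unknown parents
#'   are encoded as `"0"`, `NA` or `""`.
#' @return an object of class `lof_pedigree`: a data frame in topological
#'   order (parents precede offspring) with character `id`, `sire`, `dam`
#'   (`NA` for unknown), `sex`, `role`, plus integer columns `sire_row` and
#'   `dam_row` giving parent row positions (`NA` when unknown). The order is
#'   deterministic: among animals whose parents are already placed, input
#'   order is preserved.
#'
#' Validation enforces acyclicity, existence of named parents, unique ids,
#' and parent-sex consistency (sires male, dams female).
#' @export
build_pedigree <- function(records) {
  req <- c("id", "sire", "dam", "sex", "role")
  if (!all(req %in% names(records)))
    stop("pedigree records need columns: ", paste(req, collapse = ", "))
  ped <- data.frame(
    id   = as.character(records$id),
    sire = as.character(records$sire),
    dam  = as.character(records$dam),
    sex  = as.character(records$sex),
    role = as.character(records$role),
    stringsAsFactors = FALSE
  )
  ped$sire[ped$sire %in% c("0", "", NA)] <- NA_character_
  ped$dam[ped$dam %in% c("0", "", NA)] <- NA_character_

  if (anyDuplicated(ped$id))
    stop("duplicate animal id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (!all(ped$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!all(ped$role %in% c("ancestor", "candidate")))
    stop("role must be 'ancestor' or 'candidate'")

  known <- function(p) p[!is.na(p)]
  missing_parents <- setdiff(c(known(ped$sire), known(ped$dam)), ped$id)
  if (length(missing_parents))
    stop("parent(s) not in pedigree: ", paste(missing_parents, collapse = ", "))

  sex_of <- stats::setNames(ped$sex, ped$id)
  bad_sire <- known(ped$sire)[sex_of[known(ped$sire)] != "M"]
  if (length(bad_sire))
    stop("sire(s) recorded as female: ", paste(unique(bad_sire), collapse = ", "))
  bad_dam <- known(ped$dam)[sex_of[known(ped$dam)] != "F"]
  if (length(bad_dam))
    stop("dam(s) recorded as male: ", paste(unique(bad_dam), collapse = ", "))

  # Kahn's algorithm, stable in input order -> deterministic topological sort
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  placed <- rep(FALSE, n)
  order_out <- integer(0)
  repeat {
    ready <- which(!placed &
                   (is.na(si) | placed[si]) &
                   (is.na(di) | placed[di]))
    if (!length(ready)) break
    order_out <- c(order_out, ready)
    placed[ready] <- TRUE
  }
  if (length(order_out) < n) {
    stuck <- ped$id[!placed]
    stop("pedigree contains a cycle involving: ", paste(stuck, collapse = ", "))
  }
  ped <- ped[order_out, , drop = FALSE]
  rownames(ped) <- NULL
  row_of <- stats::setNames(seq_len(n), ped$id)
  ped$sire_row <- unname(ifelse(is.na(ped$sire), NA_integer_, row_of[ped$sire]))
  ped$dam_row  <- unname(ifelse(is.na(ped$dam),  NA_integer_, row_of[ped$dam]))
  class(ped) <- c("lof_pedigree", "data.frame")
  ped
}

#' @export
print.lof_pedigree <- function(x, ...) {
  cat(sprintf("<lof_pedigree> %d animals: %d ancestors, %d male / %d female candidates\n",
              nrow(x), sum(x$role == "ancestor"),
              sum(x$role == "candidate" & x$sex == "M"),
              sum(x$role == "candidate" & x$sex == "F")))
  invisible(x)
}

#' Read / write the pedigree CSV dialect
#'
#' Columns `id,sire,dam,sex,role`, header required, sentinel `0` for an
#' unknown parent.
#' @param file path to a CSV file.
#' @return `read_pedigree()` returns a [build_pedigree()] result.
#' @export
read_pedigree <- function(file) {
  build_pedigree(utils::read.csv(file, colClasses = "character"))
}

#' @rdname read_pedigree
#' @param ped a `lof_pedigree`.
#' @export
write_pedigree <- function(ped, file) {
  out <- as.data.frame(ped)[c("id", "sire", "dam", "sex", "role")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Kinship (coancestry) matrix by the tabular method
#'
#' Recursive tabular kinship: for animal `j` with parents `s`, `d` (unknown
#' parents contribute zero, i.e. are treated as unique unrelated non-inbred
#' founders), `f(i, j) = (f(i, s) + f(i, d)) / 2` for earlier animals `i`, and
#' `f(j, j) = (1 + f(s, d)) / 2`. The inbreeding coefficient of `j` is
#' `F_j = f(s, d)`, and the diagonal is `0.5 * (1 + F_j)`.
#'
#' @param ped a `lof_pedigree`.
#' @return a symmetric numeric matrix with dimnames = animal ids.
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- ped$sire_row
  di <- ped$dam_row
  for (j in seq_len(n)) {
    if (j > 1L) {
      i <- seq_len(j - 1L)
      fs <- if (is.na(si[j])) 0 else f[si[j], i]
      fd <- if (is.na(di[j])) 0 else f[di[j], i]
      fij <- (fs + fd) / 2
      f[j, i] <- fij
      f[i, j] <- fij
    }
    fsd <- if (is.na(si[j]) || is.na(di[j])) 0 else f[si[j], di[j]]
    f[j, j] <- (1 + fsd) / 2
  }
  f
}

#' Inbreeding coefficient of the progeny of each mating
#'
#' The inbreeding coefficient of the offspring of sire `s` and dam `d` equals
#' their kinship `f(s, d)`.
#' @param kin a kinship matrix from [kinship_matrix()].
#' @param matings a data frame with character columns `sire`, `dam`.
#' @return numeric vector of progeny inbreeding coefficients.
#' @export
progeny_inbreeding <- function(kin, matings) {
  kin[cbind(as.character(matings$sire), as.character(matings$dam))]
}

#' Parental coancestry of a mating list
#'
#' Mean kinship weighted by parental contributions: `x' K x` where `x_i` is
#' the contribution proportion of parent `i`. Contributions are scaled so
#' that each sex sums to 1/2 (the standard optimal-contribution convention:
#' `x_i = n_i / (2 N)` with `n_i` matings for parent `i` out of `N`), so a
#' single unrelated non-inbred sire-dam pair gives 0.25. Self-kinship
#' diagonal terms are included. The convention is recorded in the
#' `"convention"` attribute of the result.
#'
#' @param kin kinship matrix (dimnames = ids covering all mated parents).
#' @param matings data frame with columns `sire`, `dam`.
#' @return the coancestry value in `[0, (1 + max F) / 2]`.
#' @export
parental_coancestry <- function(kin, matings) {
  if (nrow(matings) == 0L) stop("empty mating list")
  n <- nrow(matings)
  use <- table(c(as.character(matings$sire), as.character(matings$dam)))
  ids <- names(use)
  if (!all(ids %in% rownames(kin)))
    stop("mating list contains animals absent from the kinship matrix")
  x <- as.numeric(use) / (2 * n)
  val <- drop(x %*% kin[ids, ids, drop = FALSE] %*% x)
  attr(val, "convention") <-
    "x_i = n_i / (2 N); each sex sums to 1/2; diagonal self-kinship included"
  val
}
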