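## Space-group operator table.  Only a small set of common
## low-symmetry groups is needed: the synthetic crystals use P1 and P21 and
## the detection pipeline only requires the rotational (Laue) parts for
## intensity expansion and Patterson symmetry.

.sg_table <- local({
  I3 <- diag(3)
  rot2y <- diag(c(-1, 1, -1))     # 2-fold along b
  rot2x <- diag(c(1, -1, -1))
  rot2z <- diag(c(-1, -1, 1))
  list(
    "P 1" = list(ops = list(list(R = I3, t = c(0, 0, 0)))),
    "P 1 2 1" = list(ops = list(
      list(R = I3, t = c(0, 0, 0)),
      list(R = rot2y, t = c(0, 0, 0)))),
    "P 1 21 1" = list(ops = list(
      list(R = I3, t = c(0, 0, 0)),
      list(R = rot2y, t = c(0, 0.5, 0)))),
    "P 21 21 21" = list(ops = list(
      list(R = I3, t = c(0, 0, 0)),
      list(R = rot2z, t = c(0.5, 0, 0.5)),
      list(R = rot2y, t = c(0, 0.5, 0.5)),
      list(R = rot2x, t = c(0.5, 0.5, 0))))
  )
})

.sg_aliases <- c(
  "P1" = "P 1", "P 1" = "P 1",
  "P2" = "P 1 2 1", "P 1 2 1" = "P 1 2 1", "P121" = "P 1 2 1",
  "P21" = "P 1 21 1", "P 21" = "P 1 21 1", "P 1 21 1" = "P 1 21 1",
  "P1211" = "P 1 21 1",
  "P212121" = "P 21 21 21", "P 21 21 21" = "P 21 21 21")

#' Space-group symmetry information
#'
#' Look up a space group by Hermann-Mauguin symbol and return its symmetry
#' operations and Laue-group rotations.  Supported groups: P1, P2, P21 and
#' P212121 (the low-symmetry groups in which translational
#' noncrystallographic symmetry is overwhelmingly observed).
#'
#' @param symbol Hermann-Mauguin symbol, with or without spaces
#'   (e.g. `"P 21 21 21"` or `"P212121"`).
#' @return An object of class `space_group` with components:
#'   `symbol` (canonical HM symbol); `ops`, a list of symmetry operations,
#'   each a list with 3x3 rotational part `R` and fractional translation
#'   `t`; `laue`, the list of distinct rotation matrices of the Laue group
#'   (point-group rotations closed under inversion, so Friedel symmetry is
#'   included); and `n_ops`, the number of symmetry operations.
#' @examples
#' sg <- space_group("P21")
#' sg$n_ops
#' @export
space_group <- function(symbol) {
  key <- toupper(gsub("[_]", "", symbol))
  canon <- .sg_aliases[match(key, names(.sg_aliases))]
  if (is.na(canon)) {
    key2 <- gsub(" ", "", key)
    canon <- .sg_aliases[match(key2, gsub(" ", "", names(.sg_aliases)))]
  }
  if (is.na(canon))
    stop("unsupported space group symbol: ", symbol,
         " (supported: P1, P2, P21, P212121)")
  canon <- unname(canon)
  ops <- .sg_table[[canon]]$ops
  # Laue rotations: distinct rotational parts, closed under inversion
  rots <- lapply(ops, `[[`, "R")
  rots <- c(rots, lapply(rots, function(R) -R))
  key_of <- vapply(rots, function(R) paste(as.integer(round(R)), collapse = ","), "")
  laue <- rots[!duplicated(key_of)]
  structure(list(symbol = canon, ops = ops, laue = laue,
                 n_ops = length(ops)),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("Space group %s: %d symmetry operations, %d Laue rotations\n",
              x$symbol, x$n_ops, length(x$laue)))
  invisible(x)
}

#' Expand Miller indices under the Laue group
#'
#' Applies every Laue rotation (inversion included) to a set of unique
#' Miller indices, returning the full sphere of symmetry-equivalent
#' indices with the parent row index attached.
#'
#' @param sg a [space_group()].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @return A list with `hkl` (m x 3 matrix of expanded indices, duplicates
#'   removed) and `parent` (length-m row index into the input).
#' @export
expand_hkl_laue <- function(sg, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  out <- vector("list", length(sg$laue))
  for (i in seq_along(sg$laue)) {
    # reciprocal-space action of a rotation R on h is h %*% R
    out[[i]] <- cbind(hkl %*% sg$laue[[i]], seq_len(nrow(hkl)))
  }
  all <- do.call(rbind, out)
  key <- paste(all[, 1], all[, 2], all[, 3])
  keep <- !duplicated(key)
  list(hkl = all[keep, 1:3, drop = FALSE], parent = all[keep, 4])
}

#' Reduce Miller indices to a canonical asymmetric unit
#'
#' Maps each index to a canonical representative under the Laue group
#' (Friedel inversion included): the lexicographically greatest equivalent
#' on (h, k, l).  This fixed choice makes reduced index sets comparable
#' across the package.
#'
#' @param sg a [space_group()].
#' @param hkl n x 3 integer matrix.
#' @return n x 3 matrix of canonical representatives (may contain
#'   duplicates if the input did).
#' @export
reduce_hkl <- function(sg, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  best <- hkl
  for (R in sg$laue) {
    cand <- hkl %*% R
    swap <- (cand[, 1] > best[, 1]) |
      (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
      (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
    best[swap, ] <- cand[swap, , drop = FALSE]
  }
  best
}
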