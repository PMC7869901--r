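#' Chain model
#'
#' A single polypeptide chain reduced to one coordinate per residue
#' (C-alpha), as used by the coordinate-space TNCS analysis.
#'
#' @param id chain identifier.
#' @param sequence character vector of one-letter residue codes, one per
#'   residue.
#' @param xyz n x 3 matrix of orthogonal coordinates (Angstrom).
#' @param weight total scattering weight of the chain (default: number of
#'   residues).
#' @return Object of class `chain_model`.
#' @export
chain_model <- function(id, sequence, xyz, weight = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  if (length(sequence) != nrow(xyz))
    stop("sequence length and coordinate count differ for chain ", id)
  if (nrow(xyz) < 3) stop("chain ", id, " has fewer than 3 residues")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in chain ", id)
  structure(list(id = id, sequence = sequence, xyz = xyz,
                 weight = if (is.null(weight)) nrow(xyz) else weight),
            class = "chain_model")
}

#' Coordinate model of an asymmetric unit
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @param chains list of [chain_model()] objects.
#' @return Object of class `coord_model`.
#' @export
coord_model <- function(cell, sg, chains) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  structure(list(cell = cell, sg = sg, chains = chains), class = "coord_model")
}

#' Read a coordinate model from a PDB file
#'
#' Parses the CRYST1 record for cell and space group, takes C-alpha atoms
#' per chain, and honours MTRIX records (when flagged as not already
#' applied) by generating the additional noncrystallographic copies.
#'
#' @param path PDB file path.
#' @return A [coord_model()].
#' @export
read_coords_pdb <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("PDB file lacks a CRYST1 record: ", path)
  cell <- unit_cell(as.numeric(substr(cr[1], 7, 15)),
                    as.numeric(substr(cr[1], 16, 24)),
                    as.numeric(substr(cr[1], 25, 33)),
                    as.numeric(substr(cr[1], 34, 40)),
                    as.numeric(substr(cr[1], 41, 47)),
                    as.numeric(substr(cr[1], 48, 54)))
  sg <- space_group(trimws(substr(cr[1], 56, 66)))

  at <- grep("^ATOM  |^HETATM", lines, value = TRUE)
  name <- trimws(substr(at, 13, 16))
  ca <- at[name == "CA"]
  if (!length(ca)) stop("no C-alpha atoms found in ", path)
  ch <- substr(ca, 22, 22)
  res <- trimws(substr(ca, 18, 20))
  xyz <- cbind(as.numeric(substr(ca, 31, 38)),
               as.numeric(substr(ca, 39, 46)),
               as.numeric(substr(ca, 47, 54)))
  chains <- lapply(unique(ch), function(id) {
    sel <- ch == id
    chain_model(id, aa3to1(res[sel]), xyz[sel, , drop = FALSE])
  })

  # MTRIX reconstruction: rows with iGiven != 1 generate extra copies
  mt <- grep("^MTRIX[123]", lines, value = TRUE)
  if (length(mt) >= 3) {
    serials <- unique(as.integer(substr(mt, 8, 10)))
    extra <- list()
    for (sn in serials) {
      rows <- mt[as.integer(substr(mt, 8, 10)) == sn]
      if (length(rows) != 3) next
      given <- any(trimws(substr(rows, 60, 60)) == "1")
      if (given) next
      R <- t(vapply(rows, function(r) c(as.numeric(substr(r, 11, 20)),
                                        as.numeric(substr(r, 21, 30)),
                                        as.numeric(substr(r, 31, 40))), numeric(3)))
      tv <- vapply(rows, function(r) as.numeric(substr(r, 46, 55)), 0)
      for (chm in chains) {
        extra <- c(extra, list(chain_model(paste0(chm$id, sn),
                                           chm$sequence,
                                           t(R %*% t(chm$xyz)) +
                                             matrix(tv, nrow(chm$xyz), 3, byrow = TRUE))))
      }
    }
    chains <- c(chains, extra)
  }
  coord_model(cell, sg, chains)
}

## three-letter to one-letter residue codes (unknowns -> X)
aa3to1 <- function(res) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- tab[res]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Match chains by sequence identity
#'
#' Pairs of chains whose global pairwise sequence identity reaches the
#' threshold over an aligned length of at least `min_aligned` residues.
#' Alignment uses Biostrings global alignment (BLOSUM62).
#'
#' @param model a [coord_model()].
#' @param identity_threshold fractional identity required (default 0.95).
#' @param min_aligned minimum aligned length in residues (default 20,
#'   relaxed to the chain length for shorter synthetic chains).
#' @return Data frame with columns `i`, `j` (chain indices) and
#'   `identity`.
#' @export
match_chains <- function(model, identity_threshold = 0.95, min_aligned = 20) {
  ch <- model$chains
  if (length(ch) < 2)
    return(data.frame(i = integer(0), j = integer(0), identity = numeric(0)))
  out <- NULL
  for (i in seq_along(ch)) for (j in seq_along(ch)) {
    if (j <= i) next
    id <- sequence_identity(ch[[i]]$sequence, ch[[j]]$sequence)
    min_len <- min(min_aligned, length(ch[[i]]$sequence), length(ch[[j]]$sequence))
    if (!is.na(id["identity"]) && id["identity"] >= identity_threshold &&
        id["aligned"] >= min_len)
      out <- rbind(out, data.frame(i = i, j = j, identity = unname(id["identity"])))
  }
  if (is.null(out)) data.frame(i = integer(0), j = integer(0), identity = numeric(0))
  else out
}

## fractional identity and aligned length of two residue-code vectors
sequence_identity <- function(a, b) {
  sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
  al <- tryCatch(
    Biostrings::pairwiseAlignment(Biostrings::AAString(sa), Biostrings::AAString(sb),
                                  type = "global", substitutionMatrix = "BLOSUM62",
                                  gapOpening = 10, gapExtension = 0.5),
    error = function(e) NULL)
  if (is.null(al)) {
    # fall back to positional comparison for exotic residue codes
    n <- min(nchar(sa), nchar(sb))
    return(c(identity = mean(substring(sa, 1:n, 1:n) == substring(sb, 1:n, 1:n)),
             aligned = n))
  }
  c(identity = Biostrings::pid(al, type = "PID1") / 100,
    aligned = Biostrings::nchar(al))
}

#' Least-squares superposition of a chain pair under every symmetry operation
#'
#' For each symmetry operation s of the space group, superposes chain A
#' onto s(B) over matched C-alpha atoms (Kabsch algorithm) and reports the
#' residual rotation angle and the fractional translation taking A to
#' s(B).  The operation with the smallest residual rotation is the TNCS
#' candidate.
#'
#' @param chainA,chainB [chain_model()] objects with the same residue
#'   count (sequence-matched chains).
#' @param sg a [space_group()].
#' @param cell a [unit_cell()].
#' @return Data frame with one row per symmetry operation: `op`,
#'   `angle_deg`, `t1`, `t2`, `t3` (fractional translation) and `rmsd_fit`
#'   (coordinate r.m.s.d. after superposition).
#' @export
superpose_pair <- function(chainA, chainB, sg, cell) {
  nA <- nrow(chainA$xyz); nB <- nrow(chainB$xyz)
  n <- min(nA, nB)
  if (n < 3) stop("need at least 3 matched residues")
  A <- chainA$xyz[seq_len(n), , drop = FALSE]
  B0 <- chainB$xyz[seq_len(n), , drop = FALSE]
  # degenerate (collinear) coordinate sets cannot define a rotation
  if (min(svd(scale(A, scale = FALSE))$d) < 1e-6)
    stop("degenerate (collinear) atom set in chain ", chainA$id)
  out <- NULL
  for (k in seq_along(sg$ops)) {
    op <- sg$ops[[k]]
    Bf <- t(op$R %*% t(orth_to_frac(cell, B0))) +
      matrix(op$t, n, 3, byrow = TRUE)
    B <- frac_to_orth(cell, Bf)
    fit <- kabsch(A, B)
    tf <- orth_to_frac(cell, fit$t_centroid)
    out <- rbind(out, data.frame(op = k, angle_deg = fit$angle,
                                 t1 = tf[1], t2 = tf[2], t3 = tf[3],
                                 rmsd_fit = fit$rmsd))
  }
  out
}

## Kabsch superposition of A onto B: rotation U minimizing |U(A-cA)-(B-cB)|;
## angle is the residual rotation, t_centroid the centroid shift cB - cA.
kabsch <- function(A, B) {
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  H <- t(A0) %*% B0
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  U <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  res <- B0 - t(U %*% t(A0))
  list(U = U, angle = rotation_angle(U), t_centroid = cB - cA,
       rmsd = sqrt(mean(rowSums(res^2))))
}

#' Assemble closed TNCS groups from within-tolerance chain pairs
#'
#' Builds the graph of chain pairs whose minimal superposition rotation is
#' within the angular tolerance and whose translation is non-trivial, and
#' takes its transitive closure: every connected component forms a closed
#' group even when some member pairs exceed the tolerance individually.
#' A component is reported as a TNCS group when its member translations
#' are successive multiples of a basic vector (within `trans_tol`
#' fractional per axis, minimum-image).
#'
#' @param pairs data frame with columns `i`, `j`, `angle_deg`, `t1`, `t2`,
#'   `t3` (minimal-rotation superposition results per matched pair).
#' @param model the [coord_model()] the pairs refer to.
#' @param r_deg angular tolerance in degrees.
#' @param trans_tol translation-multiple tolerance, fractional per axis.
#' @param min_t_orth minimum orthogonal translation length (Angstrom) for
#'   a pair to count as translationally related.
#' @return List of TNCS groups; each is a list with `members` (chain ids),
#'   `order`, `t_frac`, `t_orth`, `t_length`, `max_rotation_deg` and
#'   `scattering_fraction`.
#' @export
build_closed_groups <- function(pairs, model, r_deg, trans_tol = 0.05,
                                min_t_orth = 1.0) {
  nch <- length(model$chains)
  if (!nrow(pairs)) return(list())
  tlen <- min_image_dist(model$cell, as.matrix(pairs[, c("t1", "t2", "t3")]))
  edge <- pairs$angle_deg <= r_deg & tlen >= min_t_orth
  if (!any(edge)) return(list())
  # union-find over chains
  parent <- seq_len(nch)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in which(edge)) {
    a <- find(pairs$i[r]); b <- find(pairs$j[r])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(nch), find, 0L)
  groups <- list()
  total_w <- sum(vapply(model$chains, `[[`, 0, "weight"))
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2) next
    sub <- pairs[pairs$i %in% members & pairs$j %in% members, , drop = FALSE]
    # basic vector: shortest within-tolerance edge translation
    esub <- sub[sub$angle_deg <= r_deg, , drop = FALSE]
    el <- min_image_dist(model$cell, as.matrix(esub[, c("t1", "t2", "t3")]))
    esub <- esub[el >= min_t_orth, , drop = FALSE]
    el <- el[el >= min_t_orth]
    if (!nrow(esub)) next
    tb <- as.numeric(esub[which.min(el), c("t1", "t2", "t3")])
    # every member translation from a reference must be ~ m * tb
    ok <- TRUE
    ref <- members[1]
    for (mbr in members[-1]) {
      rsel <- (sub$i == ref & sub$j == mbr) | (sub$i == mbr & sub$j == ref)
      if (!any(rsel)) next
      tv <- as.numeric(sub[which(rsel)[1], c("t1", "t2", "t3")])
      if (sub$i[which(rsel)[1]] != ref) tv <- -tv
      ismul <- FALSE
      for (m in seq_len(length(members) - 1)) {
        dev1 <- tv - m * tb
        dev2 <- -tv - m * tb
        if (all(abs(dev1 - round(dev1)) <= trans_tol) ||
            all(abs(dev2 - round(dev2)) <= trans_tol)) {
          ismul <- TRUE; break
        }
      }
      if (!ismul) { ok <- FALSE; break }
    }
    if (!ok) next
    tb_wrapped <- tb - round(tb)
    groups <- c(groups, list(list(
      members = vapply(model$chains[members], `[[`, "", "id"),
      order = length(members),
      t_frac = tb_wrapped,
      t_orth = frac_to_orth(model$cell, tb_wrapped),
      t_length = min_image_dist(model$cell, tb),
      max_rotation_deg = max(sub$angle_deg),
      scattering_fraction = sum(vapply(model$chains[members], `[[`, 0, "weight")) / total_w)))
  }
  groups[order(-vapply(groups, `[[`, 0, "order"))]
}

#' Coordinate-space TNCS classifier
#'
#' The coordinates-based test for TNCS at angular tolerance `r_deg`:
#' sequence-matched chains are superposed under every symmetry operation,
#' pairs whose minimal residual rotation is within tolerance are assembled
#' into closed groups, and TNCS is declared when any group of order >= 2
#' exists.
#'
#' @param model a [coord_model()].
#' @param r_deg angular tolerance in degrees (default 10).
#' @param identity_threshold sequence-identity threshold for chain
#'   matching.
#' @param trans_tol translation-multiple tolerance (fractional).
#' @return A list with `has_tncs` (logical), `groups` (see
#'   [build_closed_groups()]) and `pairs` (all superposition candidates).
#' @export
pdb_tncs <- function(model, r_deg = 10, identity_threshold = 0.95,
                     trans_tol = 0.05) {
  stopifnot(inherits(model, "coord_model"))
  if (length(model$chains) < 2)
    return(list(has_tncs = FALSE, groups = list(),
                pairs = data.frame()))
  matched <- match_chains(model, identity_threshold)
  if (!nrow(matched))
    return(list(has_tncs = FALSE, groups = list(), pairs = data.frame()))
  best <- NULL
  for (r in seq_len(nrow(matched))) {
    i <- matched$i[r]; j <- matched$j[r]
    sp <- tryCatch(superpose_pair(model$chains[[i]], model$chains[[j]],
                                  model$sg, model$cell),
                   error = function(e) NULL)
    if (is.null(sp)) next
    k <- which.min(sp$angle_deg)
    best <- rbind(best, data.frame(i = i, j = j, sp[k, , drop = FALSE]))
  }
  if (is.null(best))
    return(list(has_tncs = FALSE, groups = list(), pairs = data.frame()))
  groups <- build_closed_groups(best, model, r_deg, trans_tol)
  list(has_tncs = length(groups) > 0, groups = groups, pairs = best)
}

#' Convert a synthetic crystal to a coordinate model
#'
#' Each TNCS copy becomes one chain (alanine pseudo-sequence), so the
#' coordinate-space analysis can be run against the generator's ground
#' truth.
#'
#' @param cry a [generate_crystal()] result.
#' @return A [coord_model()].
#' @export
crystal_to_model <- function(cry) {
  xyz <- frac_to_orth(cry$cell, cry$xyz_frac)
  chains <- lapply(seq_len(cry$n), function(m) {
    sel <- cry$copy == m
    chain_model(LETTERS[m], rep("A", sum(sel)), xyz[sel, , drop = FALSE])
  })
  coord_model(cry$cell, cry$sg, chains)
}
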