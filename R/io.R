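#' Read merged reflection data from a file
#'
#' Reads structure-factor mmCIF (`_refln` loop) or a CSV reflection table
#' and builds a [reflection_set()].  Provenance is inferred from the
#' available columns in the order mean intensity, anomalous intensity,
#' amplitude; amplitude data default to the French-Wilson provenance
#' unless `amplitude_raw = TRUE`.
#'
#' CSV files need columns `h,k,l` plus one of: `I,sigI`;
#' `Iplus,sigIplus,Iminus,sigIminus`; `F,sigF`; and cell/symmetry header
#' lines of the form `# cell a b c alpha beta gamma` and
#' `# spacegroup SYMBOL` before the table.
#'
#' @param path file path.
#' @param format `"sf-cif"` or `"csv"`; guessed from the extension when
#'   missing (`.cif` / `.csv`).
#' @param amplitude_raw logical; when amplitudes are the only data, treat
#'   them as plain |F| (provenance `"amplitude-raw"`) instead of
#'   French-Wilson output.
#' @return A [reflection_set()].
#' @export
load_reflections <- function(path, format = c("auto", "sf-cif", "csv"),
                             amplitude_raw = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "sf-cif" else "csv"
  }
  if (format == "sf-cif") read_sf_cif(path, amplitude_raw) else read_refl_csv(path, amplitude_raw)
}

build_rs_from_table <- function(cell, sg, tab, amplitude_raw) {
  hkl <- as.matrix(tab[, c("h", "k", "l")])
  has <- function(x) x %in% names(tab) && any(is.finite(tab[[x]]))
  if (has("I")) {
    reflection_set(cell, sg, hkl, I = tab$I,
                   sigI = if (has("sigI")) tab$sigI else NULL,
                   provenance = "mean-intensity")
  } else if (has("Iplus") || has("Iminus")) {
    reflection_set(cell, sg, hkl,
                   Iplus = tab$Iplus, sigIplus = tab$sigIplus,
                   Iminus = tab$Iminus, sigIminus = tab$sigIminus,
                   provenance = "anomalous-intensity")
  } else if (has("F")) {
    reflection_set(cell, sg, hkl, F = tab$F,
                   sigF = if (has("sigF")) tab$sigF else NULL,
                   provenance = if (amplitude_raw) "amplitude-raw"
                                else "amplitude-french-wilson")
  } else stop("no intensity or amplitude columns found in ", deparse(substitute(tab)))
}

read_refl_csv <- function(path, amplitude_raw = FALSE) {
  lines <- readLines(path)
  cl <- grep("^#\\s*cell\\b", lines, value = TRUE)
  sl <- grep("^#\\s*spacegroup\\b", lines, value = TRUE)
  if (!length(cl) || !length(sl))
    stop("CSV reflection file lacks '# cell' or '# spacegroup' header: ", path)
  cv <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", cl[1])), "\\s+")[[1]])
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  sg <- space_group(trimws(sub("^#\\s*spacegroup", "", sl[1])))
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  build_rs_from_table(cell, sg, tab, amplitude_raw)
}

#' Write a reflection set as CSV
#'
#' Plain-text reflection table with cell and space-group header comments,
#' readable by [load_reflections()].
#'
#' @param rs a [reflection_set()].
#' @param path output file path.
#' @export
write_refl_csv <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# cell %.6f %.6f %.6f %.6f %.6f %.6f\n",
              rs$cell$a, rs$cell$b, rs$cell$c,
              rs$cell$alpha, rs$cell$beta, rs$cell$gamma), file = con)
  cat(sprintf("# spacegroup %s\n", rs$sg$symbol), file = con)
  tab <- data.frame(h = rs$hkl[, 1], k = rs$hkl[, 2], l = rs$hkl[, 3])
  for (f in c("I", "sigI", "Iplus", "sigIplus", "Iminus", "sigIminus", "F", "sigF"))
    if (!is.null(rs[[f]])) tab[[f]] <- rs[[f]]
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- structure-factor mmCIF ----

read_sf_cif <- function(path, amplitude_raw = FALSE) {
  lines <- readLines(path)
  val <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA)
    v <- trimws(sub(paste0("^", tag), "", ln[1]))
    gsub("^'|'$", "", v)
  }
  cv <- suppressWarnings(as.numeric(c(
    val("_cell.length_a"), val("_cell.length_b"), val("_cell.length_c"),
    val("_cell.angle_alpha"), val("_cell.angle_beta"), val("_cell.angle_gamma"))))
  if (any(is.na(cv))) stop("sf-mmCIF file lacks a complete _cell block: ", path)
  sym <- val("_symmetry.space_group_name_H-M")
  if (is.na(sym)) sym <- val("_space_group.name_H-M_alt")
  if (is.na(sym)) stop("sf-mmCIF file lacks a space-group symbol: ", path)
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  sg <- space_group(sym)

  # locate the _refln loop
  loop_starts <- grep("^loop_", lines)
  tab <- NULL
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_refln\\.", tags))) next
    rows <- character(0)
    while (i <= length(lines) && nzchar(trimws(lines[i])) &&
           !grepl("^(loop_|_|#)", lines[i])) {
      rows <- c(rows, lines[i]); i <- i + 1
    }
    fields <- strsplit(trimws(rows), "\\s+")
    m <- do.call(rbind, fields)
    if (ncol(m) != length(tags)) stop("malformed _refln loop in ", path)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- tags
    tab <- df
    break
  }
  if (is.null(tab)) stop("no _refln loop found in ", path)
  num <- function(tag) {
    if (!tag %in% names(tab)) return(NULL)
    suppressWarnings(as.numeric(sub("^\\?$", "NA", tab[[tag]])))
  }
  out <- data.frame(h = num("_refln.index_h"), k = num("_refln.index_k"),
                    l = num("_refln.index_l"))
  grab <- list(I = "_refln.intensity_meas", sigI = "_refln.intensity_sigma",
               Iplus = "_refln.pdbx_I_plus", sigIplus = "_refln.pdbx_I_plus_sigma",
               Iminus = "_refln.pdbx_I_minus", sigIminus = "_refln.pdbx_I_minus_sigma",
               F = "_refln.F_meas_au", sigF = "_refln.F_meas_sigma_au")
  for (nm in names(grab)) {
    v <- num(grab[[nm]])
    if (!is.null(v)) out[[nm]] <- v
  }
  build_rs_from_table(cell, sg, out, amplitude_raw)
}

#' Write a reflection set as structure-factor mmCIF
#'
#' Minimal sf-mmCIF with cell, symmetry and a `_refln` loop carrying
#' whichever data columns the set holds.
#'
#' @param rs a [reflection_set()].
#' @param path output file path.
#' @param block data block name.
#' @export
write_sf_cif <- function(rs, path, block = "rtncs") {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("data_", block)
  w("#")
  w(sprintf("_cell.length_a    %.4f", rs$cell$a))
  w(sprintf("_cell.length_b    %.4f", rs$cell$b))
  w(sprintf("_cell.length_c    %.4f", rs$cell$c))
  w(sprintf("_cell.angle_alpha %.4f", rs$cell$alpha))
  w(sprintf("_cell.angle_beta  %.4f", rs$cell$beta))
  w(sprintf("_cell.angle_gamma %.4f", rs$cell$gamma))
  w(sprintf("_symmetry.space_group_name_H-M '%s'", rs$sg$symbol))
  w("#")
  w("loop_")
  cols <- list("_refln.index_h" = rs$hkl[, 1],
               "_refln.index_k" = rs$hkl[, 2],
               "_refln.index_l" = rs$hkl[, 3])
  map <- list(I = "_refln.intensity_meas", sigI = "_refln.intensity_sigma",
              Iplus = "_refln.pdbx_I_plus", sigIplus = "_refln.pdbx_I_plus_sigma",
              Iminus = "_refln.pdbx_I_minus", sigIminus = "_refln.pdbx_I_minus_sigma",
              F = "_refln.F_meas_au", sigF = "_refln.F_meas_sigma_au")
  for (nm in names(map)) if (!is.null(rs[[nm]])) cols[[map[[nm]]]] <- rs[[nm]]
  for (tag in names(cols)) w(tag)
  m <- do.call(cbind, lapply(cols, function(x) {
    if (is.numeric(x) && !all(x == round(x))) sprintf("%.10g", x)
    else format(x)
  }))
  m[is.na(do.call(cbind, cols))] <- "?"
  writeLines(apply(m, 1, paste, collapse = " "), con)
  w("#")
  invisible(path)
}
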