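# XYZ I/O for isolated molecules, with a sidecar CSV carrying the metadata
# the bare format lacks (partial charges, bonds, torsion definitions).

#' Write a molecule as XYZ plus a sidecar table
#'
#' The `.xyz` file is a standard extended-XYZ-free plain XYZ; the sidecar
#' `<path>.meta.csv` holds one row per atom (`charge`) and encodes bonds and
#' torsions in its header comment lines.
#'
#' @param mol a [molecule()].
#' @param path output path ending in `.xyz`.
#' @return `path`, invisibly.
#' @export
write_molecule_xyz <- function(mol, path) {
  n <- length(mol$elements)
  lines <- c(as.character(n), mol$id,
             sprintf("%s %.8f %.8f %.8f", mol$elements,
                     mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3]))
  writeLines(lines, path)
  meta <- file.path(paste0(path, ".meta.csv"))
  hdr <- c(paste0("# bonds: ",
                  paste(apply(mol$bonds, 1, paste, collapse = "-"),
                        collapse = " ")),
           paste0("# torsions: ",
                  paste(vapply(mol$torsions, paste, "", collapse = "-"),
                        collapse = " ")))
  con <- file(meta, "w")
  writeLines(hdr, con)
  write.csv(data.frame(atom = seq_len(n), element = mol$elements,
                       charge = mol$charges), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a molecule from XYZ plus its sidecar table
#'
#' @param path the `.xyz` path written by [write_molecule_xyz()] (the
#'   sidecar `<path>.meta.csv` must sit next to it; without it the molecule
#'   has zero charges, no bonds and no torsions).
#' @param id identifier; defaults to the XYZ comment line.
#' @return A [molecule()].
#' @export
read_molecule_xyz <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.null(id)) id <- trimws(lines[2])
  rows <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  elements <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  charges <- NULL; bonds <- NULL; torsions <- list()
  meta <- paste0(path, ".meta.csv")
  if (file.exists(meta)) {
    mlines <- readLines(meta, warn = FALSE)
    parse_idx <- function(prefix) {
      ln <- grep(prefix, mlines, value = TRUE, fixed = TRUE)
      if (!length(ln)) return(list())
      toks <- strsplit(trimws(sub(prefix, "", ln[1], fixed = TRUE)), " ")[[1]]
      toks <- toks[toks != ""]
      lapply(toks, function(t) as.integer(strsplit(t, "-")[[1]]))
    }
    b <- parse_idx("# bonds: ")
    if (length(b)) bonds <- do.call(rbind, b)
    torsions <- parse_idx("# torsions: ")
    tab <- read.csv(textConnection(mlines[!startsWith(mlines, "#")]))
    charges <- tab$charge
  }
  molecule(id, elements, xyz, bonds = bonds, charges = charges,
           torsions = torsions)
}
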