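# Core CIF 1.1 reader/writer, restricted to the tags a CSP pipeline needs:
# cell, symmetry (H-M symbol and/or explicit operator loop), atom sites.
# Unknown tags are skipped with a warning once per file.

#' Read a crystal structure from CIF text
#'
#' Parses a core CIF 1.1 block containing `_cell_length_*`/`_cell_angle_*`,
#' symmetry as either `_symmetry_space_group_name_H-M` or a
#' `_symmetry_equiv_pos_as_xyz` loop, and an `_atom_site_fract_*` loop.
#' Standard uncertainties in parentheses (`27.0723(10)`) are stripped.
#' The atom sites become a single rigid molecule placed at its centroid with
#' identity orientation (the asymmetric unit as deposited).
#'
#' @param text CIF content as a single string or character vector of lines,
#'   or a path to a `.cif` file.
#' @param bonds,charges,torsions optional molecular annotations to attach to
#'   the asymmetric-unit molecule (CIF itself carries none).
#' @return A [crystal_structure()].
#' @export
read_cif <- function(text, bonds = NULL, charges = NULL, torsions = list()) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1) text <- strsplit(text, "\n")[[1]]
  lines <- trimws(text)
  lines <- lines[lines != "" & !startsWith(lines, "#")]

  num <- function(x) as.numeric(gsub("\\(.*\\)", "", x))
  tags <- list()
  loops <- list()
  i <- 1
  unknown <- character(0)
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "data_")) { i <- i + 1; next }
    if (tolower(ln) == "loop_") {
      hdr <- character(0)
      i <- i + 1
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        hdr <- c(hdr, strsplit(lines[i], "[[:space:]]+")[[1]][1])
        i <- i + 1
      }
      rows <- list()
      while (i <= length(lines) && !startsWith(lines[i], "_") &&
             !startsWith(lines[i], "loop_") && !startsWith(lines[i], "data_")) {
        vals <- .cif_tokens(lines[i])
        if (length(vals)) rows[[length(rows) + 1]] <- vals
        i <- i + 1
      }
      loops[[length(loops) + 1]] <- list(hdr = tolower(hdr), rows = rows)
      next
    }
    if (startsWith(ln, "_")) {
      parts <- .cif_tokens(ln)
      tag <- tolower(parts[1])
      val <- if (length(parts) >= 2) paste(parts[-1], collapse = " ") else NA
      known <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                 "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma",
                 "_symmetry_space_group_name_h-m",
                 "_space_group_name_h-m_alt", "_symmetry_cell_setting",
                 "_cell_volume")
      if (!tag %in% known) unknown <- c(unknown, tag)
      tags[[tag]] <- val
    }
    i <- i + 1
  }
  if (length(unknown))
    warning("ignoring unknown CIF tag(s): ",
            paste(unique(unknown), collapse = ", "))

  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  for (tg in need) if (is.null(tags[[tg]])) stop("CIF parse error: missing tag ", tg)
  cell <- unit_cell(num(tags[["_cell_length_a"]]), num(tags[["_cell_length_b"]]),
                    num(tags[["_cell_length_c"]]),
                    alpha = if (is.null(tags[["_cell_angle_alpha"]])) 90 else num(tags[["_cell_angle_alpha"]]),
                    beta  = if (is.null(tags[["_cell_angle_beta"]]))  90 else num(tags[["_cell_angle_beta"]]),
                    gamma = if (is.null(tags[["_cell_angle_gamma"]])) 90 else num(tags[["_cell_angle_gamma"]]))

  symloop <- NULL; siteloop <- NULL
  for (lp in loops) {
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz", lp$hdr)))
      symloop <- lp
    if (any(grepl("_atom_site_fract_x", lp$hdr))) siteloop <- lp
  }
  if (is.null(siteloop)) stop("CIF parse error: missing tag _atom_site_fract_x")

  if (!is.null(symloop)) {
    col <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                symloop$hdr)[1]
    xyz_ops <- vapply(symloop$rows, function(r) r[col], "")
    symbol <- if (!is.null(tags[["_symmetry_space_group_name_h-m"]]))
      gsub("['\"]", "", tags[["_symmetry_space_group_name_h-m"]]) else "custom"
    sg <- space_group(symbol, ops = xyz_ops)
  } else {
    symtag <- tags[["_symmetry_space_group_name_h-m"]]
    if (is.null(symtag)) symtag <- tags[["_space_group_name_h-m_alt"]]
    if (is.null(symtag)) stop("CIF parse error: missing tag _symmetry_space_group_name_H-M")
    sg <- space_group(gsub("['\"]", "", symtag))
  }

  hdr <- siteloop$hdr
  ix <- match(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z"), hdr)
  lab <- match("_atom_site_label", hdr)
  typ <- match("_atom_site_type_symbol", hdr)
  frac <- t(vapply(siteloop$rows, function(r) num(r[ix]), numeric(3)))
  elements <- vapply(siteloop$rows, function(r) {
    raw <- if (!is.na(typ)) r[typ] else r[lab]
    sub("^([A-Za-z]{1,2}).*", "\\1", raw)
  }, "")
  cart <- transform_coordinates(cell, frac, "to-Cartesian")
  ctr <- colMeans(cart)
  mol <- molecule(id = "cif", elements = elements, xyz = cart,
                  bonds = bonds, charges = charges, torsions = torsions)
  fc <- as.numeric(transform_coordinates(cell, matrix(ctr, 1), "to-fractional"))
  crystal_structure(cell, sg, list(list(molecule = mol, frac = fc %% 1,
                                        quat = c(1, 0, 0, 0))))
}

.cif_tokens <- function(line) {
  out <- character(0)
  rest <- trimws(line)
  while (nchar(rest) > 0) {
    if (startsWith(rest, "'") || startsWith(rest, '"')) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "($|[[:space:]])"), substring(rest, 2))
      if (end < 0) { out <- c(out, substring(rest, 2)); break }
      out <- c(out, substr(rest, 2, end))
      rest <- trimws(substring(rest, end + 2))
    } else {
      sp <- regexpr("[[:space:]]", rest)
      if (sp < 0) { out <- c(out, rest); break }
      out <- c(out, substr(rest, 1, sp - 1))
      rest <- trimws(substring(rest, sp))
    }
  }
  out
}

#' Write a crystal structure as CIF text
#'
#' Emits the unit cell, the symmetry operator loop (and H-M symbol), and the
#' asymmetric-unit atom sites in fractional coordinates to six decimals.
#'
#' @param structure a [crystal_structure()].
#' @param path optional file path; if given the text is also written there.
#' @return The CIF text, invisibly when `path` is given.
#' @export
write_cif <- function(structure, path = NULL) {
  cell <- structure$cell
  M <- cell_matrix(cell)
  out <- c(
    "data_cocryscreen",
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    sprintf("_symmetry_space_group_name_H-M '%s'", structure$sg$symbol),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(structure$sg$ops, function(o) paste0("'", format_xyz_op(o), "'"), ""),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"
  )
  counter <- 0
  for (p in structure$asym) {
    local <- .placement_local_coords(p)
    ctr <- as.numeric(matrix(p$frac, 1) %*% M)
    cart <- sweep(local, 2, ctr, "+")
    frac <- cart %*% solve(M)
    # normalise the printed representation: wrap atoms whose centroid sits in
    # the home cell can still poke out; keep them as-is but kill signed zeros
    frac <- round(frac, 6) + 0
    for (a in seq_len(nrow(frac))) {
      counter <- counter + 1
      out <- c(out, sprintf("%s%d %s %.6f %.6f %.6f",
                            p$molecule$elements[a], counter,
                            p$molecule$elements[a],
                            frac[a, 1], frac[a, 2], frac[a, 3]))
    }
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
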