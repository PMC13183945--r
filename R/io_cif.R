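# Small-molecule CIF reader/writer.
#
# Supports the subset of the CIF dialect produced by small-molecule
# refinement programs: the _cell_* items, a symmetry loop in either the
# _symmetry_equiv_pos_as_xyz or _space_group_symop_operation_xyz spelling,
# and an _atom_site loop with fractional coordinates. Values may carry
# standard uncertainties in parentheses, e.g. "14.9474(12)".

cif_number <- function(x) {
  as.numeric(sub("\\(.*\\)", "", x))
}

strip_quotes <- function(x) {
  gsub("^['\"]|['\"]$", "", x)
}

# tokenizer honouring single/double quotes
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  strip_quotes(regmatches(line, list(m))[[1]])
}

#' Parse a symmetry operator string
#'
#' Turns an xyz-style operator such as `"-y, x-y, z+1/2"` into a rotation
#' matrix and translation vector acting on fractional coordinates.
#'
#' @param s operator string.
#' @return `list(rot = 3x3, trans = length-3)`.
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("\\s", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3L) stop("malformed symmetry operator: ", s)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        rot[r, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^\\d+/\\d+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        trans[r] <- trans[r] + sign * nm[1] / nm[2]
      } else if (grepl("^\\d*\\.?\\d+$", body)) {
        trans[r] <- trans[r] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry term '", tm, "' in operator: ", s)
      }
    }
  }
  list(rot = rot, trans = trans)
}

format_symop <- function(op) {
  ax <- c("x", "y", "z")
  row_str <- function(r) {
    out <- ""
    for (k in 1:3) {
      co <- op$rot[r, k]
      if (co == 0) next
      out <- paste0(out, if (co > 0 && nzchar(out)) "+" else if (co < 0) "-" else "", ax[k])
    }
    tr <- op$trans[r] %% 1
    if (abs(tr) > 1e-9) {
      fr <- c(`0.5` = "1/2", `0.25` = "1/4", `0.75` = "3/4",
              `0.3333333` = "1/3", `0.6666667` = "2/3")
      key <- sprintf("%.7g", tr)
      out <- paste0(out, "+", if (!is.na(fr[key])) fr[key] else sprintf("%.6f", tr))
    }
    out
  }
  paste(vapply(1:3, row_str, character(1)), collapse = ",")
}

read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  get_item <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    tok <- cif_tokens(hit[1])
    if (length(tok) < 2) NA_character_ else tok[2]
  }
  a <- cif_number(get_item("_cell_length_a"))
  b <- cif_number(get_item("_cell_length_b"))
  cc <- cif_number(get_item("_cell_length_c"))
  al <- cif_number(get_item("_cell_angle_alpha"))
  be <- cif_number(get_item("_cell_angle_beta"))
  ga <- cif_number(get_item("_cell_angle_gamma"))
  if (any(is.na(c(a, b, cc, al, be, ga)))) {
    stop("CIF file ", path, " lacks a complete _cell_ block")
  }
  cell <- unit_cell(a, b, cc, al, be, ga)

  # walk loops
  loops <- list()
  i <- 1L
  nl <- length(lines)
  while (i <= nl) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      tags <- character(0)
      i <- i + 1L
      while (i <= nl && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, cif_tokens(lines[i])[1])
        i <- i + 1L
      }
      rows <- list()
      while (i <= nl && !grepl("^\\s*(loop_|_|data_)", lines[i]) &&
             nzchar(trimws(lines[i]))) {
        tok <- cif_tokens(lines[i])
        if (length(tok) != length(tags)) {
          stop("CIF parse error at line ", i, " of ", path,
               ": expected ", length(tags), " fields, got ", length(tok))
        }
        rows[[length(rows) + 1L]] <- tok
        i <- i + 1L
      }
      if (length(rows)) {
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- tags
        loops[[length(loops) + 1L]] <- tab
      }
    } else {
      i <- i + 1L
    }
  }

  sym_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  ops <- list(symop_identity())
  for (lp in loops) {
    hit <- intersect(sym_tags, names(lp))
    if (length(hit)) {
      ops <- lapply(lp[[hit[1]]], parse_symop)
      break
    }
  }

  atom_loop <- NULL
  for (lp in loops) {
    if (all(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z") %in% names(lp))) {
      atom_loop <- lp; break
    }
  }
  if (is.null(atom_loop)) stop("CIF file ", path, " has no _atom_site loop")
  n <- nrow(atom_loop)
  el <- if ("_atom_site_type_symbol" %in% names(atom_loop)) {
    atom_loop[["_atom_site_type_symbol"]]
  } else {
    sub("[0-9'\"].*$", "", atom_loop[["_atom_site_label"]])
  }
  frac <- cbind(cif_number(atom_loop[["_atom_site_fract_x"]]),
                cif_number(atom_loop[["_atom_site_fract_y"]]),
                cif_number(atom_loop[["_atom_site_fract_z"]]))
  cart <- frac_to_cart(cell, frac)
  atoms <- data.frame(
    atom_id = seq_len(n),
    element = el,
    name = if ("_atom_site_label" %in% names(atom_loop)) atom_loop[["_atom_site_label"]] else el,
    residue = if ("_atom_site_residue" %in% names(atom_loop)) atom_loop[["_atom_site_residue"]] else "UNK",
    resid = 1L,
    molecule_id = NA_integer_,
    x = cart[, 1], y = cart[, 2], z = cart[, 3],
    stringsAsFactors = FALSE
  )
  crystal_structure(atoms, cell, ops, provenance = paste0("cif:", path),
                    assign_molecules = FALSE)
}

write_cif <- function(structure, path) {
  at <- structure$atoms
  cell <- structure$cell
  frac <- cart_to_frac(cell, coords(structure))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_cyclohelix",
    sprintf("_cell_length_a    %.6f", cell$a),
    sprintf("_cell_length_b    %.6f", cell$b),
    sprintf("_cell_length_c    %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta  %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "loop_",
    "_space_group_symop_operation_xyz"
  ), con)
  for (op in structure$symmetry) {
    writeLines(sprintf("  '%s'", format_symop(op)), con)
  }
  writeLines(c(
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_residue",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"
  ), con)
  lab <- make.unique(at$name, sep = "_")
  lab[!nzchar(lab)] <- at$element[!nzchar(lab)]
  writeLines(sprintf("%s %s %s %.6f %.6f %.6f",
                     gsub("\\s", "_", lab), at$element,
                     gsub("\\s", "_", at$residue),
                     frac[, 1], frac[, 2], frac[, 3]), con)
  invisible(path)
}
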