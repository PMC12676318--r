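#' Read molecular structures from SMILES or SDF
#'
#' SMILES files (one molecule per line, optional name after whitespace) are
#' parsed through OpenBabel; SDF V2000 records are read from their
#' fixed-width connection tables. SDF coordinates are retained, so records
#' with 3D information double as conformers.
#'
#' @param path Path to a `.smi`/`.smiles` or `.sdf` file.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @param on_error `"skip"` drops unparseable records with a warning;
#'   `"error"` aborts on the first one.
#' @return A list of [molecule_graph()] objects.
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf"),
                            on_error = c("skip", "error")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("smi", "smiles", "txt")) "smiles" else "sdf"
  }
  out <- list()
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      mol <- try(parse_smiles(parts[1], name = if (length(parts) > 1) parts[2] else NULL),
                 silent = TRUE)
      if (inherits(mol, "try-error")) {
        if (on_error == "error") abort(paste0("invalid SMILES: ", parts[1]))
        warn(paste0("skipping invalid SMILES: ", parts[1]))
      } else {
        out[[length(out) + 1L]] <- mol
      }
    }
  } else {
    for (bl in split_sdf_records(readLines(path, warn = FALSE))) {
      mol <- try(sdf_block_to_mol(bl), silent = TRUE)
      if (inherits(mol, "try-error")) {
        if (on_error == "error") abort("invalid SDF record")
        warn("skipping invalid SDF record")
      } else {
        out[[length(out) + 1L]] <- mol
      }
    }
  }
  out
}

split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) {
    if (any(nzchar(trimws(lines)))) return(list(lines))
    return(list())
  }
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(s, e) lines[s:e], starts, ends)
}

#' Parse a single SMILES string
#'
#' @param smiles A SMILES string.
#' @param name Optional molecule name.
#' @return A `molecule_graph` (2D placeholder coordinates from OpenBabel).
#' @export
parse_smiles <- function(smiles, name = NULL) {
  txt <- suppressWarnings(try(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    silent = TRUE
  ))
  if (inherits(txt, "try-error") || !nzchar(txt)) {
    abort(paste0("SMILES parse failure: ", smiles))
  }
  mol <- sdf_block_to_mol(strsplit(txt, "\n")[[1]])
  if (n_atoms(mol) == 0) abort(paste0("SMILES parse failure: ", smiles))
  mol$name <- name %||% smiles
  attr(mol, "smiles") <- smiles
  mol
}

# Parse one SDF V2000 record from its text lines. The connection table is
# fixed-width (columns 1-3/4-6/7-9 for bonds; 1-30 coordinates, 32-34
# element for atoms); formal charges come from M CHG lines. The installed
# high-level SDF reader drops charges and mis-handles single-atom records,
# hence the direct field extraction here.
sdf_block_to_mol <- function(lines) {
  if (length(lines) < 4) abort("truncated SDF record")
  counts <- lines[4]
  n_at <- as.integer(substr(counts, 1, 3))
  n_bd <- as.integer(substr(counts, 4, 6))
  if (is.na(n_at) || is.na(n_bd)) abort("bad SDF counts line")
  if (length(lines) < 4 + n_at + n_bd) abort("truncated SDF record")
  atom_lines <- lines[seq_len(n_at) + 4L]
  coords <- matrix(0, n_at, 3)
  el <- character(n_at)
  for (i in seq_len(n_at)) {
    coords[i, 1] <- as.numeric(substr(atom_lines[i], 1, 10))
    coords[i, 2] <- as.numeric(substr(atom_lines[i], 11, 20))
    coords[i, 3] <- as.numeric(substr(atom_lines[i], 21, 30))
    el[i] <- trimws(substr(atom_lines[i], 32, 34))
  }
  if (any(is.na(coords)) || any(!nzchar(el))) abort("bad SDF atom block")
  bonds <- tibble(i = integer(), j = integer(), order = integer())
  if (n_bd > 0) {
    bond_lines <- lines[4L + n_at + seq_len(n_bd)]
    bonds <- tibble(
      i = as.integer(substr(bond_lines, 1, 3)),
      j = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
    if (any(is.na(bonds))) abort("bad SDF bond block")
  }
  charges <- integer(n_at)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    vals <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", cl)), "\\s+")[[1]])
    if (length(vals) >= 2) {
      charges[vals[seq(1, length(vals), by = 2)]] <- vals[seq(2, length(vals), by = 2)]
    }
  }
  nm <- trimws(lines[1])
  mol <- molecule_graph(tibble(element = el, charge = charges), bonds,
                        coords = coords, name = if (nzchar(nm)) nm else NULL)
  attr(mol, "sdf_text") <- paste(c(lines[!grepl("^\\$\\$\\$\\$", lines)], "$$$$"),
                                 collapse = "\n")
  mol
}

# Serialize a molecule_graph as one SDF V2000 record (text). Reuses the
# original record when the molecule came from an SDF/SMILES parse.
as_sdf_text <- function(mol) {
  txt <- attr(mol, "sdf_text")
  if (!is.null(txt)) return(txt)
  n <- n_atoms(mol)
  coords <- mol$coords %||% matrix(0, n, 3)
  header <- c(mol$name %||% "molecule", "  hitfunnel", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(mol$bonds))
  atoms <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], mol$atoms$element[i])
  }, character(1))
  bonds <- if (nrow(mol$bonds)) {
    vapply(seq_len(nrow(mol$bonds)), function(k) {
      sprintf("%3d%3d%3d  0", mol$bonds$i[k], mol$bonds$j[k], mol$bonds$order[k])
    }, character(1))
  } else character(0)
  chg_idx <- which(mol$atoms$charge != 0)
  chg <- if (length(chg_idx)) {
    sprintf("M  CHG%3d%s", length(chg_idx),
            paste0(sprintf("%4d%4d", chg_idx, mol$atoms$charge[chg_idx]), collapse = ""))
  } else character(0)
  paste(c(header, counts, atoms, bonds, chg, "M  END", "$$$$"), collapse = "\n")
}

# Run a function over the OpenBabel OBMol parsed from a molecule's SDF text.
# ChemmineOB's high-level SMARTS wrapper mis-dispatches in the installed
# build, so the low-level SWIG bindings are driven directly.
with_obmol <- function(mol, fn) {
  ob <- getNamespace("ChemmineOB")
  txt <- paste0(as_sdf_text(mol), "\n")
  conv <- ob$OBConversion(ob$istreamFromString(txt))
  if (!ob$OBConversion_SetInFormat(conv, "SDF")) abort("OpenBabel: cannot set SDF format")
  obmol <- ob$OBMol()
  if (!ob$OBConversion_Read(conv, obmol)) abort("OpenBabel failed to read molecule")
  fn(ob, obmol)
}

# Count unique SMARTS matches of `pattern` in `mol` (0 when none).
ob_smarts_count <- function(mol, pattern) {
  with_obmol(mol, function(ob, obmol) {
    sp <- ob$OBSmartsPattern()
    if (!ob$OBSmartsPattern_Init(sp, pattern)) {
      abort(paste0("malformed SMARTS pattern: ", pattern))
    }
    ob$OBSmartsPattern_Match__SWIG_1(sp, obmol)
    length(ob$OBSmartsPattern_GetUMapList(sp))
  })
}

# Validate a SMARTS pattern without matching.
ob_smarts_valid <- function(pattern) {
  ob <- getNamespace("ChemmineOB")
  sp <- ob$OBSmartsPattern()
  isTRUE(suppressWarnings(ob$OBSmartsPattern_Init(sp, pattern)))
}

# OpenBabel physchem properties (logP by atom contributions, TPSA by Ertl
# fragment contributions) for one molecule.
ob_properties <- function(mol) {
  p <- with_obmol(mol, function(ob, obmol) {
    ChemmineOB::prop_OB(list(obmol))
  })
  list(logp = as.numeric(p[1, "logP"]), tpsa = as.numeric(p[1, "TPSA"]))
}
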