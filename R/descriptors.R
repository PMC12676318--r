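#' Compute rule-of-five descriptors for a molecule
#'
#' Molecular weight is summed from standard atomic weights (implicit
#' hydrogens included); HBD counts N/O atoms bearing at least one hydrogen
#' and HBA counts all N and O atoms -- the classic Lipinski conventions.
#' logP (Wildman--Crippen-type atom contributions, i.e. the quantity BOILED-
#' Egg calls WLOGP) and TPSA (Ertl fragment contributions) come from the
#' OpenBabel descriptor engine.
#'
#' @param mol A [molecule_graph()].
#' @return A one-row tibble with columns `mw`, `hbd`, `hba`, `logp`, `tpsa`.
#' @examples
#' compute_descriptors(parse_smiles("c1ccccc1"))
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule_graph"))
  el <- mol$atoms$element
  hs <- total_h(mol)
  no <- el %in% c("N", "O")
  mw <- mol_weight(mol)   # validates elements before OpenBabel sees them
  props <- ob_properties(mol)
  tibble(
    mw = mw,
    hbd = as.integer(sum(no & hs > 0)),
    hba = as.integer(sum(no)),
    logp = props$logp,
    tpsa = props$tpsa
  )
}

#' Lipinski rule-of-five violations
#'
#' Applies the four rules with inclusive boundaries (a descriptor exactly at
#' its threshold complies): HBD <= 5, HBA <= 10, MW <= 500 g/mol, logP <= 5.
#'
#' @param desc A data frame with columns `mw`, `hbd`, `hba`, `logp`
#'   (one or more rows; extra columns pass through).
#' @return The input with logical flag columns `viol_hbd`, `viol_hba`,
#'   `viol_mw`, `viol_logp` and the total `n_violations`.
#' @export
lipinski_violations <- function(desc) {
  desc <- as_tibble(desc)
  need <- c("mw", "hbd", "hba", "logp")
  missing <- setdiff(need, names(desc))
  if (length(missing)) {
    abort(paste0("descriptor table missing: ", paste(missing, collapse = ", ")))
  }
  if (nrow(desc) && !all(is.finite(as.matrix(desc[need])))) {
    abort("descriptors must be finite")
  }
  desc |>
    mutate(
      viol_hbd = .data$hbd > 5,
      viol_hba = .data$hba > 10,
      viol_mw = .data$mw > 500,
      viol_logp = .data$logp > 5,
      n_violations = as.integer(.data$viol_hbd) + as.integer(.data$viol_hba) +
        as.integer(.data$viol_mw) + as.integer(.data$viol_logp)
    )
}
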