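# Pharmacophore typing: which feature classes (donor, acceptor, aromatic,
# hydrophobe, cation, anion) occur in a molecule. Rules are SMARTS
# patterns shipped as an editable YAML config.

PHARMACOPHORE_TYPES <- c("donor", "acceptor", "aromatic", "hydrophobe",
                         "cation", "anion")

pharmacophore_config <- local({
  cache <- NULL
  function(path = NULL) {
    if (!is.null(path)) return(yaml::read_yaml(path))
    if (is.null(cache)) {
      p <- system.file("extdata", "pharmacophore_smarts.yaml", package = "csmol")
      if (!nzchar(p)) p <- file.path("inst", "extdata", "pharmacophore_smarts.yaml")
      cache <<- yaml::read_yaml(p)
    }
    cache
  }
})

#' Pharmacophore feature types present in a molecule
#'
#' @param mol a `csmol_molecule`
#' @param config optional list `type -> SMARTS patterns`; defaults to the
#'   shipped rules
#' @return character vector, subset of
#'   `c("donor","acceptor","aromatic","hydrophobe","cation","anion")`
#' @export
pharmacophore_types <- function(mol, config = pharmacophore_config()) {
  stopifnot(inherits(mol, "csmol_molecule"))
  mb <- ob_smiles_to_molblock(mol$smiles)
  present <- vapply(names(config), function(type) {
    any(vapply(config[[type]],
               function(p) ob_smarts_count(mb, p) > 0, logical(1)))
  }, logical(1))
  names(config)[present]
}
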