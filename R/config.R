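# Plain-text (YAML) configuration for the simulator and the pipeline CLI.

#' Read a simulator configuration file
#'
#' The YAML file may set any [simConfig()] argument; `fusions` is a list of
#' blocks with `donor_gene`, `donor_exon`, `acceptor_gene`, `acceptor_exon`,
#' `samples`, and optionally `expression_fold` and `junction_reads`.
#'
#' @param path YAML path
#' @return a [SimConfig-class]
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  fus <- lapply(y$fusions, function(f)
    fusionSpec(f$donor_gene, f$donor_exon, f$acceptor_gene, f$acceptor_exon,
               samples = unlist(f$samples),
               expressionFold = if (is.null(f$expression_fold)) 10
                                else f$expression_fold,
               junctionReads = if (is.null(f$junction_reads)) 5
                               else f$junction_reads))
  args <- y[setdiff(names(y), "fusions")]
  map <- c(seed = "seed", n_samples = "nSamples", n_genes = "nGenes",
           n_chroms = "nChroms", chrom_len = "chromLen",
           fragment_median_bp = "fragmentMedianBp",
           fragment_sdlog = "fragmentSdlog", read_len = "readLen",
           premrna_fraction = "premrnaFraction",
           contaminant_fraction = "contaminantFraction", depth = "depth",
           directional = "directional")
  call <- list()
  for (nm in names(args)) {
    key <- if (nm %in% names(map)) map[[nm]] else nm
    call[[key]] <- args[[nm]]
  }
  call$fusions <- fus
  do.call(simConfig, call)
}

#' Read pipeline parameters from a YAML file
#'
#' Keys mirror the arguments of [gfuseParams()]; unknown keys are an error.
#'
#' @param path YAML path (NULL gives the defaults)
#' @return parameter list
#' @export
readParamsConfig <- function(path = NULL) {
  if (is.null(path)) return(gfuseParams())
  y <- yaml::read_yaml(path)
  known <- names(formals(gfuseParams))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  do.call(gfuseParams, y)
}
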