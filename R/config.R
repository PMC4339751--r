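#' Evaluation configuration
#'
#' All domain thresholds and controlled-vocabulary sets the nine evidence
#' evaluation functions depend on, in one config object. Defaults follow the
#' aging-domain rule set: the five aging-related GO process terms, the
#' WormBase lifespan phenotype classes, the high-confidence PSI-MI
#' interaction-detection methods, a 0.05 significance cutoff for expression
#' evidence, and a minimum co-occurrence count of 1 (any observed
#' co-occurrence with an aging term counts). Every slot can be overridden
#' from a YAML file so that rule behaviour changes without code changes.
#'
#' @param ... Named overrides of the default slots.
#' @return A list of class `"ageval_config"`.
#' @section Slots:
#' \describe{
#'   \item{aging_go_terms}{GO identifiers counted as aging-related process
#'     annotations: aging (go:0007568), cell aging (go:0007569),
#'     age-dependent behavioral decline (go:0035982), multicellular
#'     organismal aging (go:0010259), determination of adult lifespan
#'     (go:0008340).}
#'   \item{lifespan_phenotypes}{Phenotype classes meaning a perturbation of
#'     the gene extends or shortens lifespan.}
#'   \item{high_confidence_methods}{PSI-MI detection-method codes accepted as
#'     high-confidence evidence for a physical interaction.}
#'   \item{experimental_evidence}{ECO evidence classes counted as
#'     experimental for GO annotations.}
#'   \item{expression_p_threshold}{p-value below which a fold change counts
#'     as significant differential expression (sign of the change is
#'     ignored).}
#'   \item{cooccurrence_min_count}{Minimum GO-term co-occurrence count.}
#'   \item{genage_positive_effect}{Curated lifespan effect string that
#'     satisfies the curated-annotation check.}
#'   \item{genage_count_decrease}{If `TRUE`, a curated "decrease" effect also
#'     counts as an aging association.}
#' }
#' @examples
#' cfg <- default_config(expression_p_threshold = 0.01)
#' cfg$expression_p_threshold
#' @export
default_config <- function(...) {
  cfg <- list(
    aging_go_terms = c("go:0007568", "go:0007569", "go:0035982",
                       "go:0010259", "go:0008340"),
    lifespan_phenotypes = c("wbphenotype:0000061",   # extended life span
                            "wbphenotype:0000062",   # shortened life span
                            "wbphenotype:0000039"),  # life span variant
    high_confidence_methods = c("psi-mi:0397", "psi-mi:0398",
                                "psi-mi:0676", "psi-mi:0109"),
    experimental_evidence = c("eco:0000006", "eco:0000269", "eco:0000314",
                              "eco:0000315", "eco:0000316"),
    expression_p_threshold = 0.05,
    cooccurrence_min_count = 1L,
    genage_positive_effect = "increase",
    genage_count_decrease = FALSE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config slots: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "ageval_config"))
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$aging_go_terms) >= 1)
  if (!is.numeric(cfg$expression_p_threshold) ||
      cfg$expression_p_threshold <= 0 || cfg$expression_p_threshold >= 1) {
    stop("expression_p_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$cooccurrence_min_count < 1) {
    stop("cooccurrence_min_count must be a positive integer", call. = FALSE)
  }
  cfg
}

#' @rdname default_config
#' @param path Path to a YAML file whose top-level keys are config slots.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}
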