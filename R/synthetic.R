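#' Synthetic knowledge bases with plantable evidence profiles
#'
#' The generator builds a fully self-contained knowledge base across all
#' seven graph roles, planting for each synthetic gene exactly the facts
#' that make each of the nine evidence evaluation functions return a chosen
#' boolean — a 9-bit mask per gene — and recording the planted ground truth
#' in a ledger. Helper entities needed to satisfy the interaction-based
#' checks (interaction partners, their proteins and annotations) are drawn
#' from a dedicated per-gene helper pool that is never itself scored, so
#' planting evidence for one gene never changes another gene's verdicts and
#' per-gene outcomes stay independent. Masks are sampled independently per
#' function with the configured satisfaction probabilities; the defaults are
#' the per-function satisfaction proportions observed across the C. elegans
#' gene complement (DEF1..DEF9: 6.6e-3, 1.3e-1, 2.1e-5, 1.1e-3, 1.4e-2,
#' 1.8e-2, 2.8e-3, 2.5e-2, 1.4e-1).
#'
#' @name synthetic
NULL

#' @describeIn synthetic Default per-function satisfaction probabilities.
#' @export
def_satisfaction_defaults <- function() {
  c(6.6e-3, 1.3e-1, 2.1e-5, 1.1e-3, 1.4e-2, 1.8e-2, 2.8e-3, 2.5e-2, 1.4e-1)
}

#' @describeIn synthetic A planted per-gene evidence profile. `mask` is a
#'   logical vector of length 9 (intended verdict of each evaluation
#'   function); `refuting_decrease` additionally plants a curated "decrease"
#'   lifespan record, a refuting fact that must not satisfy the
#'   curated-annotation check.
#' @param mask Logical vector of length 9, or an integer vector of function
#'   ids to satisfy (e.g. `c(2, 7, 8, 9)`).
#' @param gene,symbol Optional identifiers; minted from the gene's position
#'   when omitted.
#' @param refuting_decrease Plant a refuting curated "decrease" record?
#' @export
synthetic_profile <- function(mask, gene = NULL, symbol = NULL,
                              refuting_decrease = FALSE) {
  if (is.numeric(mask) && !all(mask %in% c(0, 1)) ||
      (is.numeric(mask) && length(mask) != 9L)) {
    ids <- as.integer(mask)
    stopifnot(all(ids %in% 1:9))
    mask <- seq_len(9L) %in% ids
  }
  mask <- as.logical(mask)
  if (length(mask) != 9L || anyNA(mask)) {
    stop("a profile mask holds exactly 9 booleans", call. = FALSE)
  }
  structure(list(gene = gene, symbol = symbol, mask = mask,
                 refuting_decrease = isTRUE(refuting_decrease)),
            class = "synthetic_profile")
}

#' @describeIn synthetic Generator settings.
#' @param n_genes Number of randomly profiled genes.
#' @param satisfaction_probs Nine probabilities in `[0, 1]`.
#' @param explicit_profiles Optional list of [synthetic_profile()]s appended
#'   after the random genes.
#' @param seed Integer seed; the same spec and seed give an identical
#'   knowledge base and ledger.
#' @export
generator_spec <- function(n_genes, satisfaction_probs = def_satisfaction_defaults(),
                           explicit_profiles = NULL, seed = 1L) {
  stopifnot(n_genes >= 0)
  if (length(satisfaction_probs) != 9L ||
      any(satisfaction_probs < 0 | satisfaction_probs > 1)) {
    stop("configuration error: satisfaction_probs must be 9 values in [0, 1]",
         call. = FALSE)
  }
  for (p in explicit_profiles) stopifnot(inherits(p, "synthetic_profile"))
  structure(list(n_genes = as.integer(n_genes),
                 satisfaction_probs = satisfaction_probs,
                 explicit_profiles = explicit_profiles,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

plant_gene <- function(i, gene, symbol, mask, refuting_decrease, cfg, rng) {
  acc <- list()
  add <- function(g, s, p, o, literal = FALSE, datatype = NULL) {
    acc[[length(acc) + 1L]] <<- quads(g, s, p, o, literal, datatype)
  }
  tag <- sprintf("%05d", i)
  prot <- mint("uniprot", paste0("SYNP", tag))

  add("wormbase", gene, WB("approved_gene_name"), symbol, literal = TRUE)
  add("goa", prot, GO_V("gene_symbol"), symbol, literal = TRUE)

  if (mask[1]) {
    add("genage", mint("genage", paste0("s", tag)), GA("gene_symbol"),
        symbol, literal = TRUE)
    add("genage", mint("genage", paste0("s", tag)), GA("lifespan_effect"),
        "increase", literal = TRUE)
  }
  if (refuting_decrease) {
    add("genage", mint("genage", paste0("d", tag)), GA("gene_symbol"),
        symbol, literal = TRUE)
    add("genage", mint("genage", paste0("d", tag)), GA("lifespan_effect"),
        "decrease", literal = TRUE)
  }

  plant_expression <- function(p_value, suffix) {
    fc <- mint("expression", paste0("fc", tag, suffix))
    add("expression", fc, EX("gene"), gene)
    add("expression", fc, EX("cosmid"), paste0("SYNC", tag, ".1"),
        literal = TRUE)
    add("expression", fc, EX("fold_change"),
        round(rng$signed_fold(), 3), literal = TRUE, datatype = "decimal")
    add("expression", fc, EX("p_value"), signif(p_value, 4),
        literal = TRUE, datatype = "decimal")
    add("expression", fc, EX("experiment"), "geo:GSE36041")
    add("expression", fc, EX("derived_from"),
        mint("expression", paste0("ev", tag, suffix, "a")))
    add("expression", fc, EX("derived_from"),
        mint("expression", paste0("ev", tag, suffix, "b")))
  }
  if (mask[2]) {
    plant_expression(rng$sig_p(), "s")
  } else if (rng$coin()) {
    # a measured but non-significant change: exercises the threshold
    plant_expression(rng$nonsig_p(), "n")
  }

  if (mask[3]) {
    hom <- mint("ncbigene", paste0("9", tag))
    add("gendr", gene, GD("homolog"), hom)
    add("gendr", hom, GD("member_of"), GENDR_MULTISTUDY_LIST)
  }
  if (mask[4]) add("gendr", gene, GD("member_of"), GENDR_ESSENTIAL_LIST)
  if (mask[5]) add("wormbase", gene, WB("phenotype"), cfg$lifespan_phenotypes[1])

  if (mask[6]) {
    ann <- mint("wormbase", paste0("ann6_", tag))
    add("wormbase", gene, WB("go_annotation"), ann)
    add("wormbase", ann, WB("go_term"), "go:0008340")
    add("wormbase", ann, WB("evidence"), cfg$experimental_evidence[2])
  }

  if (mask[7]) {
    helper_prot <- mint("uniprot", paste0("HELP", tag))
    int <- mint("irefindex", paste0("int", tag))
    add("ppi", int, IX("interactor_a"), prot)
    add("ppi", int, IX("interactor_b"), helper_prot)
    add("ppi", int, IX("method"), cfg$high_confidence_methods[1])
    add("ppi", int, IX("article_count"), 1L, literal = TRUE,
        datatype = "integer")
    hann <- mint("goa", paste0("hann", tag))
    add("goa", helper_prot, GO_V("go_annotation"), hann)
    add("goa", hann, GO_V("go_term"), "go:0008340")
    add("goa", hann, GO_V("aspect"), "process", literal = TRUE)
  }

  if (mask[8]) {
    helper_gene <- mint("wormbase", paste0("HELPG", tag))
    add("wormbase", gene, WB("interacts_with"), helper_gene)
    add("wormbase", helper_gene, WB("phenotype"), cfg$lifespan_phenotypes[1])
  }

  if (mask[9]) {
    term <- mint("go", paste0("9", sprintf("%06d", i)))
    ann <- mint("wormbase", paste0("ann9_", tag))
    add("wormbase", gene, WB("go_annotation"), ann)
    add("wormbase", ann, WB("go_term"), term)
    add("wormbase", ann, WB("evidence"), "eco:0000501")  # electronic, non-exp
    cooc <- mint("gocooc", paste0("c", tag))
    add("go_cooccurrence", cooc, CO("term_a"), term)
    add("go_cooccurrence", cooc, CO("term_b"), "go:0008340")
    add("go_cooccurrence", cooc, CO("count"), 3L, literal = TRUE,
        datatype = "integer")
  }
  do.call(rbind, acc)
}

#' @describeIn synthetic Generate the knowledge base. Returns
#'   `list(kb, ledger)` where the ledger records the planted ground truth:
#'   one row per gene with columns `gene`, `symbol`, `def1`..`def9`,
#'   `refuting_decrease`. The facts planted for a gene are necessary and
#'   sufficient for each evaluation function to return exactly its mask bit
#'   under [default_config()].
#' @param spec A [generator_spec()].
#' @export
generate_kb <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  cfg <- default_config()
  set.seed(spec$seed)
  rng <- list(
    sig_p = function() stats::runif(1, 1e-5, 0.04),
    nonsig_p = function() stats::runif(1, 0.1, 0.9),
    coin = function() stats::runif(1) < 0.5,
    signed_fold = function() stats::runif(1, -3, 3)
  )
  masks <- matrix(stats::runif(spec$n_genes * 9L) <
                    rep(spec$satisfaction_probs, each = spec$n_genes),
                  nrow = spec$n_genes)
  profiles <- lapply(seq_len(spec$n_genes), function(i) {
    synthetic_profile(masks[i, ])
  })
  profiles <- c(profiles, spec$explicit_profiles)

  ledger_rows <- vector("list", length(profiles))
  quad_blocks <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    gene <- if (is.null(p$gene)) mint("wormbase", sprintf("SYNG%05d", i))
            else p$gene
    symbol <- if (is.null(p$symbol)) sprintf("syng-%d", i) else p$symbol
    quad_blocks[[i]] <- plant_gene(i, gene, symbol, p$mask,
                                   p$refuting_decrease, cfg, rng)
    row <- data.frame(gene = gene, symbol = symbol, stringsAsFactors = FALSE)
    for (k in 1:9) row[[paste0("def", k)]] <- p$mask[k]
    row$refuting_decrease <- p$refuting_decrease
    ledger_rows[[i]] <- row
  }
  kb <- kb_new()
  if (length(quad_blocks)) kb <- kb_add(kb, do.call(rbind, quad_blocks))
  ledger <- if (length(ledger_rows)) do.call(rbind, ledger_rows)
            else data.frame(gene = character(), symbol = character(),
                            stringsAsFactors = FALSE)
  list(kb = kb, ledger = ledger)
}

#' @describeIn synthetic Write the seven source graphs as Turtle files plus
#'   the ledger as TSV into a directory.
#' @param kb A knowledge base.
#' @param ledger The generator ledger (optional).
#' @param dir Output directory, created if missing.
#' @export
kb_export <- function(kb, dir, ledger = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in kb_graphs(kb)) {
    kb_write_turtle(kb, g, file.path(dir, paste0(g, ".ttl")))
  }
  if (!is.null(ledger)) {
    utils::write.table(ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
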