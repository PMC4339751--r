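# Vocabulary used across the seven source graphs. Predicate namespaces follow
# the convention that predicates live in a "<dataset>_vocabulary" namespace of
# the dataset they occur in.

WB <- function(p) mint("wormbase_vocabulary", p)
GA <- function(p) mint("genage_vocabulary", p)
GD <- function(p) mint("gendr_vocabulary", p)
IX <- function(p) mint("irefindex_vocabulary", p)
GO_V <- function(p) mint("goa_vocabulary", p)
EX <- function(p) mint("expression_vocabulary", p)
CO <- function(p) mint("gocooc_vocabulary", p)
HV <- function(p) mint("hypothesis_vocabulary", p)
PV <- function(p) mint("evaluation_vocabulary", p)

# graph roles
GRAPH_ROLES <- c("wormbase", "genage", "gendr", "ppi", "goa",
                 "expression", "go_cooccurrence")

# gendr membership list nodes
GENDR_MULTISTUDY_LIST <- "gendr:dr_expression_multi_study"
GENDR_ESSENTIAL_LIST <- "gendr:dr_essential"

AGING_EVENT_TYPE <- "go:0007568"
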