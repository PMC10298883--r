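#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# gene symbols are matched case-insensitively after uppercasing + trimming
normalizeSymbols <- function(x) toupper(trimws(as.character(x)))

#' AggregatedNetwork: a deduplicated physical-PPI network with an ORF roster
#'
#' Holds the unique undirected physical interactions aggregated across
#' sources, together with the roster of target ORF proteins whose
#' subinteractomes are under study. Each edge is an unordered gene pair
#' carrying the union of source tags that reported it; self-loops are
#' removed during aggregation (the count of removals is kept).
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB}
#'   (uppercased symbols, \code{geneA < geneB} lexicographically) and
#'   \code{sources} (source tags collapsed with \code{";"}).
#' @slot orfRoster character vector of roster gene symbols. Roster members
#'   need not appear in any edge (such members are "orphans").
#' @slot nSelfLoopsDropped integer count of self-loop records removed.
#'
#' @seealso [aggregateNetwork()], [subinteractome()], [partnerCensus()]
#' @export
setClass("AggregatedNetwork",
  representation(
    edges = "data.frame",
    orfRoster = "character",
    nSelfLoopsDropped = "integer"
  ),
  prototype(
    edges = data.frame(geneA = character(), geneB = character(),
                       sources = character(), stringsAsFactors = FALSE),
    orfRoster = character(),
    nSelfLoopsDropped = 0L
  )
)

setValidity("AggregatedNetwork", function(object) {
  ed <- object@edges
  msgs <- character()
  if (!all(c("geneA", "geneB", "sources") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns geneA, geneB, sources")
  else {
    if (any(ed$geneA == ed$geneB))
      msgs <- c(msgs, "self-loop edges are not allowed")
    if (any(!nzchar(ed$sources)))
      msgs <- c(msgs, "every edge must carry at least one source tag")
    if (any(ed$geneA > ed$geneB))
      msgs <- c(msgs, "edges must be stored with geneA < geneB")
    key <- paste(ed$geneA, ed$geneB)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges present; aggregation must deduplicate")
  }
  if (anyDuplicated(object@orfRoster))
    msgs <- c(msgs, "orfRoster contains duplicates")
  if (length(msgs)) msgs else TRUE
})

#' Subinteractome: the partner set of one target protein
#'
#' The set of all known protein partners that physically interact with a
#' target (ORF) protein in an aggregated network.
#'
#' @slot orf gene symbol of the target protein.
#' @slot partners character vector of partner symbols (never contains the
#'   target itself).
#' @export
setClass("Subinteractome",
  representation(orf = "character", partners = "character"))

setValidity("Subinteractome", function(object) {
  if (length(object@orf) != 1L || !nzchar(object@orf))
    return("orf must be a single non-empty symbol")
  if (object@orf %in% object@partners)
    return("target protein cannot be its own partner")
  if (anyDuplicated(object@partners))
    return("partners must be unique")
  TRUE
})

#' @describeIn Subinteractome constructor.
#' @param orf gene symbol of the target protein.
#' @param partners character vector of partner symbols.
#' @export
Subinteractome <- function(orf, partners = character()) {
  new("Subinteractome", orf = normalizeSymbols(orf),
      partners = normalizeSymbols(partners))
}

#' ExpressionMatrix: a genes x samples expression matrix for one tissue
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper carrying a
#' single \code{expr} assay (e.g. log2(TPM+1)) plus the tissue and
#' condition (normal or tumor) it was measured in.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  if (is.null(rownames(object)))
    msgs <- c(msgs, "gene symbols must be set as rownames")
  else if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "no gene may be listed twice")
  cond <- metadata(object)$condition
  if (is.null(cond) || !cond %in% c("normal", "tumor"))
    msgs <- c(msgs, "condition must be 'normal' or 'tumor'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ExpressionMatrix constructor.
#' @param values numeric matrix, genes in rows (rownames are symbols),
#'   samples in columns.
#' @param condition \code{"normal"} or \code{"tumor"}.
#' @param tissue free-text tissue / cohort label.
#' @export
ExpressionMatrix <- function(values, condition = c("normal", "tumor"),
                             tissue = "") {
  condition <- match.arg(condition)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  rownames(values) <- normalizeSymbols(rownames(values))
  se <- SummarizedExperiment(
    assays = list(expr = values),
    metadata = list(condition = condition, tissue = tissue))
  new("ExpressionMatrix", se)
}

#' @describeIn ExpressionMatrix the expression values (genes x samples).
#' @param x an \code{ExpressionMatrix}.
#' @export
exprValues <- function(x) assay(x, "expr")

#' @describeIn ExpressionMatrix condition label ("normal"/"tumor").
#' @export
exprCondition <- function(x) metadata(x)$condition

#' @describeIn ExpressionMatrix tissue label.
#' @export
exprTissue <- function(x) metadata(x)$tissue

#' SurvivalCohort: per-patient follow-up with gene expression
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay holds the
#' genes x patients expression matrix and whose column data carry
#' follow-up time in months and the event indicator (1 = death/relapse
#' observed, 0 = censored).
#'
#' @export
setClass("SurvivalCohort", contains = "SummarizedExperiment")

setValidity("SurvivalCohort", function(object) {
  cd <- colData(object)
  msgs <- character()
  if (!all(c("time", "event") %in% names(cd)))
    return("colData must contain 'time' and 'event'")
  if (any(cd$time < 0)) msgs <- c(msgs, "time must be >= 0")
  if (!all(cd$event %in% c(0, 1))) msgs <- c(msgs, "event must be 0/1")
  if (is.null(rownames(object)))
    msgs <- c(msgs, "gene symbols must be set as rownames")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SurvivalCohort constructor.
#' @param expression numeric matrix, genes x patients, rownames = symbols.
#' @param time numeric vector of follow-up times (months, >= 0).
#' @param event 0/1 vector; 1 = event observed, 0 = censored.
#' @param patientIds optional patient identifiers (default from columns).
#' @export
SurvivalCohort <- function(expression, time, event, patientIds = NULL) {
  expression <- as.matrix(expression)
  if (is.null(patientIds))
    patientIds <- colnames(expression) %||% paste0("P", seq_len(ncol(expression)))
  colnames(expression) <- patientIds
  rownames(expression) <- normalizeSymbols(rownames(expression))
  se <- SummarizedExperiment(
    assays = list(expr = expression),
    colData = DataFrame(time = as.numeric(time), event = as.numeric(event),
                        row.names = patientIds))
  new("SurvivalCohort", se)
}

#' @describeIn SurvivalCohort follow-up times in months.
#' @param x a \code{SurvivalCohort}.
#' @export
survTime <- function(x) colData(x)$time

#' @describeIn SurvivalCohort 0/1 event indicators.
#' @export
survEvent <- function(x) colData(x)$event

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DECallMatrix: ternary differential-expression calls across cancers
#'
#' Gene x cancer matrices of log2 fold-changes (tumor over normal),
#' p-values and the resulting ternary calls \code{up}/\code{down}/\code{ns}
#' (\code{NA} where the input cell is missing). Calls obey the gates
#' |log2FC| >= threshold (boundary inclusive) and p < cutoff.
#'
#' @slot log2fc numeric genes x cancers matrix (may contain \code{NA}).
#' @slot p numeric genes x cancers matrix (may contain \code{NA}).
#' @slot call character genes x cancers matrix over
#'   \code{c("up","down","ns", NA)}.
#' @slot fcThreshold,pCut the gates the calls were made with.
#' @seealso [deCallMatrix()], [cancerSpecificGenes()], [panCancerGroup()]
#' @export
setClass("DECallMatrix",
  representation(log2fc = "matrix", p = "matrix", call = "matrix",
                 fcThreshold = "numeric", pCut = "numeric"))

setValidity("DECallMatrix", function(object) {
  d <- dim(object@log2fc)
  if (!identical(d, dim(object@p)) || !identical(d, dim(object@call)))
    return("log2fc, p and call matrices must share dimensions")
  if (nrow(object@log2fc) > 0 && ncol(object@log2fc) > 0 &&
      (is.null(rownames(object@log2fc)) || is.null(colnames(object@log2fc))))
    return("log2fc needs gene rownames and cancer colnames")
  if (anyDuplicated(rownames(object@log2fc)))
    return("no gene may be listed twice")
  ok <- object@call %in% c("up", "down", "ns") | is.na(object@call)
  if (!all(ok)) return("calls must be up/down/ns/NA")
  # the call gates must hold wherever a directional call was made
  up <- !is.na(object@call) & object@call == "up"
  dn <- !is.na(object@call) & object@call == "down"
  if (any(object@log2fc[up] < object@fcThreshold) ||
      any(object@p[up] >= object@pCut))
    return("an 'up' call violates its gates")
  if (any(object@log2fc[dn] > -object@fcThreshold) ||
      any(object@p[dn] >= object@pCut))
    return("a 'down' call violates its gates")
  TRUE
})

#' @describeIn DECallMatrix genes (rownames).
#' @param x a \code{DECallMatrix}.
#' @export
deGenes <- function(x) rownames(x@log2fc)

#' @describeIn DECallMatrix cancer codes (colnames).
#' @export
deCancers <- function(x) colnames(x@log2fc)

#' @describeIn DECallMatrix the ternary call matrix.
#' @export
deCalls <- function(x) x@call

setMethod("show", "AggregatedNetwork", function(object) {
  ed <- object@edges
  nodes <- unique(c(ed$geneA, ed$geneB))
  onRoster <- object@orfRoster[object@orfRoster %in% nodes]
  cat("AggregatedNetwork:", nrow(ed), "unique physical PPIs,",
      length(nodes), "proteins\n")
  cat("  ORF roster:", length(object@orfRoster), "targets (",
      length(onRoster), "with >=1 partner )\n")
  orfOrf <- sum(ed$geneA %in% object@orfRoster & ed$geneB %in% object@orfRoster)
  cat("  ORF-ORF edges:", orfOrf,
      "| self-loops dropped:", object@nSelfLoopsDropped, "\n")
})

setMethod("show", "Subinteractome", function(object) {
  cat("Subinteractome of", object@orf, "-", length(object@partners),
      "partners\n")
  if (length(object@partners)) {
    shown <- utils::head(object@partners, 8L)
    cat(" ", paste(shown, collapse = ", "),
        if (length(object@partners) > 8L) "..." else "", "\n")
  }
})

#' @describeIn Subinteractome number of partners.
#' @param x a \code{Subinteractome}.
#' @export
subSize <- function(x) length(x@partners)

#' @describeIn Subinteractome partner symbols.
#' @export
subPartners <- function(x) x@partners

#' @describeIn Subinteractome target symbol.
#' @export
subOrf <- function(x) x@orf

#' @describeIn AggregatedNetwork all node symbols in the network.
#' @param x an \code{AggregatedNetwork}.
#' @export
networkNodes <- function(x) sort(unique(c(x@edges$geneA, x@edges$geneB)))

#' @describeIn AggregatedNetwork the edge table.
#' @export
networkEdges <- function(x) x@edges

#' @describeIn AggregatedNetwork the ORF roster.
#' @export
orfRoster <- function(x) x@orfRoster
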