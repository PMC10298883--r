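#' Parse physical protein-protein interaction records
#'
#' Reads one interaction file into a table of binary physical-interaction
#' records with a gene symbol on each side. Two dialects are supported:
#' \describe{
#'   \item{\code{mitab}}{PSI-MITAB 2.5/2.7: >= 15 tab-separated columns,
#'     interactor identifiers in columns 1-2 and aliases in columns 5-6.
#'     For each interactor the first alias annotated \code{(gene name)}
#'     wins; a line in which either side has no gene-name alias is skipped
#'     and counted.}
#'   \item{\code{tsv_edges}}{a plain 2-3 column table: geneA, geneB and an
#'     optional per-line source tag. A header row is detected when the
#'     first row does not look like a pair of gene symbols.}
#' }
#'
#' @param path path to the file.
#' @param dialect \code{"mitab"} or \code{"tsv_edges"}.
#' @param source source tag attached to every record from this file
#'   (defaults to the file name); a third TSV column overrides it per line.
#' @return data.frame with columns \code{geneA}, \code{geneB},
#'   \code{source}, \code{evidence} (always \code{"physical"}), and an
#'   attribute \code{nSkipped} counting malformed/unresolvable lines.
#' @examples
#' f <- tempfile()
#' writeLines(c("C1orf94\tC1orf109", "C1orf52\tCXorf56"), f)
#' parseInteractions(f, "tsv_edges")
#' @export
parseInteractions <- function(path, dialect = c("mitab", "tsv_edges"),
                              source = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read interaction file: ", path)
  if (is.null(source)) source <- basename(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  skipped <- 0L
  recs <- list()
  if (dialect == "tsv_edges" && length(lines)) {
    first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 2 && looksLikeHeader(first[1:2]))
      lines <- lines[-1L]
  }
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (dialect == "mitab") {
      if (length(fields) < 15) {
        warning("malformed MITAB line skipped (", length(fields),
                " columns): ", substr(ln, 1, 60))
        skipped <- skipped + 1L
        next
      }
      a <- mitabGeneName(fields[5])
      b <- mitabGeneName(fields[6])
      if (is.na(a) || is.na(b)) { skipped <- skipped + 1L; next }
    } else {
      if (length(fields) < 2 || !nzchar(trimws(fields[1])) ||
          !nzchar(trimws(fields[2]))) {
        warning("malformed edge line skipped: ", substr(ln, 1, 60))
        skipped <- skipped + 1L
        next
      }
      a <- fields[1]; b <- fields[2]
      if (length(fields) >= 3 && nzchar(trimws(fields[3])))
        src <- trimws(fields[3])
      else src <- source
    }
    recs[[length(recs) + 1L]] <- c(
      normalizeSymbols(a), normalizeSymbols(b),
      if (dialect == "mitab") source else src)
  }
  out <- if (length(recs)) {
    m <- do.call(rbind, recs)
    data.frame(geneA = m[, 1], geneB = m[, 2], source = m[, 3],
               evidence = "physical", stringsAsFactors = FALSE)
  } else {
    data.frame(geneA = character(), geneB = character(),
               source = character(), evidence = character(),
               stringsAsFactors = FALSE)
  }
  attr(out, "nSkipped") <- skipped
  out
}

# first alias annotated "(gene name)" in a MITAB alias field, NA if none
mitabGeneName <- function(field) {
  if (is.na(field) || field == "-" || !nzchar(field)) return(NA_character_)
  for (al in strsplit(field, "|", fixed = TRUE)[[1]]) {
    if (grepl("\\(gene name\\)", al)) {
      val <- sub("\\(.*$", "", al)
      val <- sub("^[^:]*:", "", val)
      val <- gsub("\"", "", val)
      if (nzchar(trimws(val))) return(trimws(val))
    }
  }
  NA_character_
}

# a 2-token row is a header when either token is not symbol-shaped or is
# a conventional column name
looksLikeHeader <- function(tokens) {
  symish <- grepl("^[A-Za-z0-9][A-Za-z0-9.-]*$", trimws(tokens))
  conventional <- grepl("^(gene|symbol|interactor|protein|source|from|to)",
                        trimws(tokens), ignore.case = TRUE)
  any(!symish) || all(conventional)
}

#' Read an ORF roster (one gene symbol per line)
#'
#' @param path text file, one symbol per line; blank lines and lines
#'   starting with \code{#} are ignored.
#' @return character vector of unique uppercased symbols.
#' @export
readRoster <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalizeSymbols(x))
}

#' Aggregate interaction records into a deduplicated network
#'
#' Merges any number of record tables (from [parseInteractions()] or
#' built in code) into one undirected network: pairs are unordered, the
#' same pair reported by several sources becomes a single edge carrying
#' the union of source tags, and self-loops are dropped (counted in the
#' returned object). Aggregation is idempotent.
#'
#' @param recordLists a data.frame of records or a list of them.
#' @param orfRoster character vector of target ORF symbols (non-empty).
#' @return an [AggregatedNetwork-class] object.
#' @examples
#' recs <- data.frame(geneA = c("A", "B"), geneB = c("B", "A"),
#'                    source = c("s1", "s2"))
#' aggregateNetwork(recs, orfRoster = "A")
#' @export
aggregateNetwork <- function(recordLists, orfRoster) {
  orfRoster <- unique(normalizeSymbols(orfRoster))
  if (!length(orfRoster) || !all(nzchar(orfRoster)))
    stop("orfRoster must be a non-empty set of gene symbols")
  if (is.data.frame(recordLists)) recordLists <- list(recordLists)
  all <- do.call(rbind, lapply(recordLists, function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(geneA = normalizeSymbols(d$geneA),
               geneB = normalizeSymbols(d$geneB),
               source = if ("source" %in% names(d)) as.character(d$source)
                        else "unspecified",
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all)) {
    return(new("AggregatedNetwork", orfRoster = orfRoster,
               nSelfLoopsDropped = 0L))
  }
  loop <- all$geneA == all$geneB
  nLoops <- sum(loop)
  if (nLoops) all <- all[!loop, , drop = FALSE]
  if (!nrow(all)) {
    return(new("AggregatedNetwork", orfRoster = orfRoster,
               nSelfLoopsDropped = as.integer(nLoops)))
  }
  a <- pmin(all$geneA, all$geneB)
  b <- pmax(all$geneA, all$geneB)
  key <- paste(a, b, sep = "\r")
  srcByKey <- split(all$source, key)
  keys <- names(srcByKey)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    geneA = vapply(parts, `[[`, "", 1L),
    geneB = vapply(parts, `[[`, "", 2L),
    sources = vapply(srcByKey, function(s)
      paste(sort(unique(s)), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  new("AggregatedNetwork", edges = edges, orfRoster = orfRoster,
      nSelfLoopsDropped = as.integer(nLoops))
}

#' Extract the subinteractome of a roster protein
#'
#' The subinteractome of a target protein is the set of all its direct
#' physical partners in the aggregated network.
#'
#' @param net an [AggregatedNetwork-class].
#' @param orf a roster gene symbol.
#' @return a [Subinteractome-class].
#' @export
subinteractome <- function(net, orf) {
  orf <- normalizeSymbols(orf)
  if (!orf %in% net@orfRoster)
    stop("'", orf, "' is not on the ORF roster")
  ed <- net@edges
  partners <- c(ed$geneB[ed$geneA == orf], ed$geneA[ed$geneB == orf])
  Subinteractome(orf, sort(unique(partners)))
}

#' Subinteractomes of every roster protein
#'
#' @param net an [AggregatedNetwork-class].
#' @param connectedOnly drop roster members without partners (default
#'   \code{FALSE}: orphans yield size-0 subinteractomes).
#' @return named list of [Subinteractome-class] objects.
#' @export
allSubinteractomes <- function(net, connectedOnly = FALSE) {
  subs <- lapply(net@orfRoster, function(o) subinteractome(net, o))
  names(subs) <- net@orfRoster
  if (connectedOnly) subs <- subs[vapply(subs, subSize, 0L) > 0L]
  subs
}

#' Census of partner sharing among roster proteins
#'
#' Classifies every non-roster partner by how many roster ORFs it binds:
#' exactly two (a potential heterotrimeric complex) or three and more (a
#' potential multimeric complex). Also reports the direct ORF-ORF edges
#' and the roster members with no known partner at all ("orphans").
#'
#' @param net an [AggregatedNetwork-class].
#' @return list with \code{orfOrfEdges} (data.frame geneA/geneB),
#'   \code{sharedByTwo}, \code{sharedByThreePlus}, \code{singleOrf}
#'   (partners of exactly one roster ORF) and \code{orphanOrfs}.
#' @export
partnerCensus <- function(net) {
  ed <- net@edges
  roster <- net@orfRoster
  aIn <- ed$geneA %in% roster
  bIn <- ed$geneB %in% roster
  orfOrf <- ed[aIn & bIn, c("geneA", "geneB"), drop = FALSE]
  rownames(orfOrf) <- NULL
  # roster neighbors of every non-roster partner
  partnerOf <- rbind(
    data.frame(partner = ed$geneB[aIn & !bIn], orf = ed$geneA[aIn & !bIn]),
    data.frame(partner = ed$geneA[bIn & !aIn], orf = ed$geneB[bIn & !aIn]))
  counts <- if (nrow(partnerOf))
    vapply(split(partnerOf$orf, partnerOf$partner),
           function(o) length(unique(o)), 0L)
  else integer()
  connected <- unique(c(ed$geneA[aIn], ed$geneB[bIn]))
  list(
    orfOrfEdges = orfOrf,
    sharedByTwo = sort(names(counts)[counts == 2L]),
    sharedByThreePlus = sort(names(counts)[counts >= 3L]),
    singleOrf = sort(names(counts)[counts == 1L]),
    orphanOrfs = sort(setdiff(roster, connected)))
}

#' Histogram of subinteractome sizes
#'
#' Bins partner counts with the convention: first bin \code{< e1},
#' interior bins half-open \code{[e_i, e_{i+1})}, the last interior bin
#' closed \code{[e_{k-1}, e_k]}, and a final open bin \code{> e_k}. With
#' the default edges this yields the bins <7, 7-15, 15-30, 30-70, 70-100
#' and >100 partners.
#'
#' @param subs list of [Subinteractome-class] objects (or an integer
#'   vector of sizes).
#' @param edges strictly increasing thresholds.
#' @return named integer vector of bin counts; sums to \code{length(subs)}.
#' @export
sizeHistogram <- function(subs, edges = c(7, 15, 30, 70, 100)) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin thresholds must be strictly increasing")
  sizes <- if (is.numeric(subs)) as.numeric(subs)
           else vapply(subs, subSize, 0L)
  k <- length(edges)
  lows <- c(-Inf, edges)
  highs <- c(edges, Inf)
  counts <- integer(k + 1L)
  for (i in seq_len(k + 1L)) {
    if (i == k) # last interior bin is closed at the top edge
      counts[i] <- sum(sizes >= lows[i] & sizes <= highs[i])
    else if (i == k + 1L)
      counts[i] <- sum(sizes > lows[i])
    else
      counts[i] <- sum(sizes >= lows[i] & sizes < highs[i])
  }
  labels <- c(paste0("<", edges[1]),
              if (k > 1) paste0("[", edges[-k], ",", edges[-1],
                                c(rep(")", k - 2L), "]")),
              paste0(">", edges[k]))
  stats::setNames(counts, labels)
}

#' Keep subinteractomes within a partner-count window
#'
#' Both bounds are inclusive; input order is preserved. The default
#' window of 7 to 100 partners balances the power of enrichment analysis
#' (enough partners) against term redundancy (not too many).
#'
#' @param subs list of [Subinteractome-class] objects.
#' @param minSize,maxSize inclusive size bounds.
#' @export
selectBySize <- function(subs, minSize = 7, maxSize = 100) {
  stopifnot(minSize >= 0, minSize <= maxSize)
  sizes <- vapply(subs, subSize, 0L)
  subs[sizes >= minSize & sizes <= maxSize]
}

#' Shortest paths between roster proteins
#'
#' Unweighted breadth-first shortest paths in the aggregated network.
#' Length 1 means a direct ORF-ORF interaction; longer paths run through
#' shared partners. Unreachable pairs get length \code{Inf} and an empty
#' path.
#'
#' @param net an [AggregatedNetwork-class].
#' @param pairs 2-column matrix/data.frame of node symbols.
#' @return data.frame with \code{from}, \code{to}, \code{length} and
#'   \code{path} (node sequence collapsed with \code{"->"}).
#' @export
shortestOrfPaths <- function(net, pairs) {
  pairs <- as.matrix(pairs)
  pairs[] <- normalizeSymbols(pairs)
  g <- asIgraph(net)
  nodes <- igraph::V(g)$name
  absent <- setdiff(unique(c(pairs)), nodes)
  if (length(absent))
    stop("node(s) absent from network: ", paste(absent, collapse = ", "))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = pairs[i, 1], to = pairs[i, 2], output = "vpath"))
    vp <- sp$vpath[[1]]
    if (length(vp) == 0)
      data.frame(from = pairs[i, 1], to = pairs[i, 2], length = Inf,
                 path = "", stringsAsFactors = FALSE)
    else
      data.frame(from = pairs[i, 1], to = pairs[i, 2],
                 length = length(vp) - 1L,
                 path = paste(igraph::V(g)$name[vp], collapse = "->"),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# igraph view of the network (nodes include isolated roster members)
asIgraph <- function(net) {
  ed <- net@edges
  verts <- unique(c(ed$geneA, ed$geneB, net@orfRoster))
  igraph::graph_from_data_frame(ed[, c("geneA", "geneB")],
                                directed = FALSE, vertices = verts)
}

#' Write a JSON summary of an aggregated network
#'
#' @param net an [AggregatedNetwork-class].
#' @param path output file.
#' @return the summary list, invisibly.
#' @export
writeNetworkSummary <- function(net, path) {
  cen <- partnerCensus(net)
  s <- list(
    nEdges = nrow(net@edges),
    nNodes = length(networkNodes(net)),
    nRoster = length(net@orfRoster),
    nOrfOrfEdges = nrow(cen$orfOrfEdges),
    nSharedByTwo = length(cen$sharedByTwo),
    nSharedByThreePlus = length(cen$sharedByThreePlus),
    nSelfLoopsDropped = net@nSelfLoopsDropped,
    orphanOrfs = cen$orphanOrfs)
  jsonlite::write_json(s, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(s)
}

#' Write subinteractomes as a 3-column TSV (orf, partner, sources)
#'
#' @param net an [AggregatedNetwork-class].
#' @param path output file.
#' @export
writeSubinteractomeTable <- function(net, path) {
  ed <- net@edges
  rows <- do.call(rbind, lapply(net@orfRoster, function(o) {
    hit <- ed$geneA == o | ed$geneB == o
    if (!any(hit)) return(NULL)
    data.frame(orf = o,
               partner = ifelse(ed$geneA[hit] == o, ed$geneB[hit],
                                ed$geneA[hit]),
               sources = ed$sources[hit], stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(orf = character(), partner = character(),
                       sources = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}
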