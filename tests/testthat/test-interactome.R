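test_that("TSV edge lists parse into symbol records", {
  f <- withr::local_tempfile()
  writeLines(c("C1orf94\tC1orf109", "C1orf52\tCXorf56"), f)
  rec <- parseInteractions(f, "tsv_edges")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$geneA, c("C1ORF94", "C1ORF52"))
  expect_equal(rec$geneB, c("C1ORF109", "CXORF56"))
  expect_equal(attr(rec, "nSkipped"), 0L)

  empty <- withr::local_tempfile()
  file.create(empty)
  rec0 <- parseInteractions(empty, "tsv_edges")
  expect_equal(nrow(rec0), 0L)
  expect_equal(attr(rec0, "nSkipped"), 0L)

  # header rows are detected and dropped
  g <- withr::local_tempfile()
  writeLines(c("gene_a\tgene_b", "TP53\tMDM2"), g)
  expect_equal(nrow(parseInteractions(g, "tsv_edges")), 1L)
})

test_that("MITAB lines resolve gene-name aliases or are skipped", {
  mkLine <- function(aliasA, aliasB) {
    fields <- rep("-", 15)
    fields[1] <- "uniprotkb:P04637"; fields[2] <- "uniprotkb:Q00987"
    fields[5] <- aliasA; fields[6] <- aliasB
    paste(fields, collapse = "\t")
  }
  f <- withr::local_tempfile()
  writeLines(c(
    mkLine("uniprotkb:TP53(gene name)|uniprotkb:p53(gene name synonym)",
           "uniprotkb:MDM2(gene name)"),
    mkLine("-", "-")), f)
  rec <- suppressWarnings(parseInteractions(f, "mitab"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$geneA, "TP53")
  expect_equal(rec$geneB, "MDM2")
  expect_equal(attr(rec, "nSkipped"), 1L)

  # short lines are malformed
  g <- withr::local_tempfile()
  writeLines("a\tb\tc", g)
  expect_warning(rec2 <- parseInteractions(g, "mitab"), "malformed")
  expect_equal(attr(rec2, "nSkipped"), 1L)
})

test_that("aggregation deduplicates unordered pairs and unions sources", {
  recs <- data.frame(
    geneA = c("A", "B", "A", "A"),
    geneB = c("B", "A", "B", "A"),
    source = c("s1", "s2", "s3", "s4"))
  net <- aggregateNetwork(recs, orfRoster = "A")
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$sources, "s1;s2;s3")
  expect_equal(net@nSelfLoopsDropped, 1L)  # the A-A record

  # idempotence: re-aggregating the aggregated edges changes nothing
  again <- aggregateNetwork(
    data.frame(geneA = ed$geneA, geneB = ed$geneB, source = ed$sources),
    orfRoster = "A")
  expect_equal(networkEdges(again)[, c("geneA", "geneB")],
               ed[, c("geneA", "geneB")])
  expect_error(aggregateNetwork(recs, character()), "non-empty")
})

test_that("the reference ORF-ORF pairs plus distractors census correctly", {
  pairs <- referenceOrfPairs()
  roster <- unique(c(pairs))
  distract <- data.frame(geneA = c("C1ORF94", "C1ORF131", "C2ORF74",
                                   "C5ORF24", "CXORF56"),
                         geneB = paste0("PARTNER", 1:5),
                         source = "x")
  recs <- rbind(data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                           source = "lit"), distract)
  net <- aggregateNetwork(recs, roster)
  expect_equal(nrow(networkEdges(net)), 13L)
  expect_equal(nrow(partnerCensus(net)$orfOrfEdges), 8L)
})

test_that("subinteractome extraction is plain adjacency", {
  leaves <- paste0("L", 1:7)
  recs <- data.frame(geneA = "HUB", geneB = leaves, source = "s")
  net <- aggregateNetwork(recs, orfRoster = c("HUB", "ISOLATED"))
  expect_equal(subSize(subinteractome(net, "HUB")), 7L)
  expect_setequal(subPartners(subinteractome(net, "HUB")), leaves)
  expect_equal(subSize(subinteractome(net, "ISOLATED")), 0L)
  expect_error(subinteractome(net, "L1"), "roster")

  # sharing a partner with another ORF does not shrink the set
  recs2 <- data.frame(geneA = c("O1", "O1", "O2"),
                      geneB = c("P1", "P2", "P1"), source = "s")
  net2 <- aggregateNetwork(recs2, orfRoster = c("O1", "O2"))
  expect_setequal(subPartners(subinteractome(net2, "O1")), c("P1", "P2"))
})

test_that("subinteractome membership is symmetric on random graphs", {
  withr::local_seed(11)
  for (rep in 1:5) {
    el <- randomEdgeList(9, 0.3)
    if (!nrow(el)) next
    nodes <- unique(c(el))
    net <- aggregateNetwork(
      data.frame(geneA = el[, 1], geneB = el[, 2], source = "r"),
      orfRoster = nodes)
    for (a in nodes) {
      for (b in subPartners(subinteractome(net, a)))
        expect_true(a %in% subPartners(subinteractome(net, b)))
    }
  }
})

test_that("partner census classifies by distinct roster neighbors", {
  recs <- data.frame(
    geneA = c("O1", "O2", "O1", "O1", "O2", "O3"),
    geneB = c("P2", "P2", "P1", "P3", "P3", "P3"),
    source = "s")
  net <- aggregateNetwork(recs, orfRoster = c("O1", "O2", "O3", "O4"))
  cen <- partnerCensus(net)
  expect_equal(cen$sharedByTwo, "P2")
  expect_equal(cen$sharedByThreePlus, "P3")
  expect_equal(cen$singleOrf, "P1")
  expect_equal(cen$orphanOrfs, "O4")
  # conservation: the three classes partition the non-roster partners
  expect_setequal(c(cen$sharedByTwo, cen$sharedByThreePlus, cen$singleOrf),
                  setdiff(networkNodes(net), orfRoster(net)))
})

test_that("census conservation holds on random bipartite-ish graphs", {
  withr::local_seed(23)
  for (rep in 1:5) {
    orfs <- paste0("O", 1:4)
    partners <- paste0("P", 1:8)
    recs <- expand.grid(geneA = orfs, geneB = partners,
                        stringsAsFactors = FALSE)
    recs <- recs[runif(nrow(recs)) < 0.3, , drop = FALSE]
    if (!nrow(recs)) next
    recs$source <- "r"
    net <- aggregateNetwork(recs, orfs)
    cen <- partnerCensus(net)
    expect_equal(length(cen$sharedByTwo) + length(cen$sharedByThreePlus) +
                   length(cen$singleOrf),
                 length(setdiff(networkNodes(net), orfs)))
  }
})

test_that("size histogram reproduces the reference distribution", {
  subs <- referenceSizeFixture()
  expect_equal(unname(sizeHistogram(subs)), c(63, 30, 40, 27, 6, 11))
  expect_equal(unname(sizeHistogram(list())), rep(0L, 6))
  expect_equal(unname(sizeHistogram(rep(7, 5)))[2], 5)
  expect_error(sizeHistogram(subs, edges = c(7, 7, 30)), "increasing")
})

test_that("histogram counts always sum to the input count", {
  withr::local_seed(5)
  for (rep in 1:20) {
    sizes <- sample(0:150, sample(1:60, 1), replace = TRUE)
    edges <- sort(sample(1:140, sample(2:6, 1)))
    expect_equal(sum(sizeHistogram(sizes, edges)), length(sizes))
  }
})

test_that("size selection is inclusive at both bounds", {
  subs <- referenceSizeFixture()
  expect_equal(length(selectBySize(subs, 7, 100)), 103L)
  expect_equal(length(selectBySize(subs, 0, Inf)), length(subs))
  mini <- lapply(c(6, 7, 100, 101), function(s)
    Subinteractome(paste0("X", s), paste0("X", s, "_", seq_len(s))))
  kept <- selectBySize(mini, 7, 100)
  expect_equal(vapply(kept, subSize, 0L), c(7L, 100L))
})

test_that("shortest ORF paths match direct/indirect/disconnected cases", {
  recs <- data.frame(geneA = c("O1", "O3", "P", "O5"),
                     geneB = c("O2", "P", "O4", "Q"),
                     source = "s")
  net <- aggregateNetwork(recs, orfRoster = c("O1", "O2", "O3", "O4", "O5"))
  sp <- shortestOrfPaths(net, rbind(c("O1", "O2"), c("O3", "O4"),
                                    c("O1", "O3")))
  expect_equal(sp$length, c(1, 2, Inf))
  expect_equal(sp$path[2], "O3->P->O4")
  expect_error(shortestOrfPaths(net, rbind(c("O1", "NOPE"))), "absent")
})

test_that("BFS path lengths equal brute-force enumeration on small graphs", {
  withr::local_seed(31)
  for (rep in 1:6) {
    el <- randomEdgeList(sample(5:12, 1), 0.25)
    if (nrow(el) < 2) next
    nodes <- unique(c(el))
    net <- aggregateNetwork(
      data.frame(geneA = el[, 1], geneB = el[, 2], source = "r"),
      orfRoster = nodes)
    pick <- replicate(4, sample(nodes, 2), simplify = FALSE)
    for (pr in pick) {
      got <- shortestOrfPaths(net, rbind(pr))$length
      expect_equal(got, bruteShortestPath(el, pr[1], pr[2]))
    }
  }
})

test_that("network summary and subinteractome tables round-trip to disk", {
  recs <- data.frame(geneA = c("O1", "O1"), geneB = c("P1", "P2"),
                     source = "s")
  net <- aggregateNetwork(recs, orfRoster = c("O1", "O2"))
  js <- withr::local_tempfile(fileext = ".json")
  s <- writeNetworkSummary(net, js)
  expect_equal(jsonlite::read_json(js)$nEdges, 2L)
  expect_equal(s$orphanOrfs, "O2")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tab <- writeSubinteractomeTable(net, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 2L)
  expect_setequal(tab$partner, c("P1", "P2"))
})
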