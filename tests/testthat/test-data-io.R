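test_that("OTU table TSV round-trip is the identity", {
  otu <- toy_otu(matrix(c(5, 0, 3, 1, 2, 8), nrow = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(otu, path)
  back <- read_otu_table(path)
  expect_equal(back, otu)
  expect_equal(dim(otu_counts(back)), c(3L, 2L))
})

test_that("OTU table validation rejects malformed input", {
  otu <- toy_otu(matrix(1:4, 2))
  dup_sample <- otu
  names(dup_sample)[3] <- "S1"
  expect_error(validate_otu_table(dup_sample), "S1")
  dup_otu <- otu
  dup_otu$otu_id <- c("A", "A")
  expect_error(validate_otu_table(dup_otu), "A")
  neg <- otu
  neg$S1[1] <- -2
  expect_error(validate_otu_table(neg), "negative")
  frac <- otu
  frac$S2[1] <- 1.5
  expect_error(validate_otu_table(frac), "non-integer")
  expect_error(validate_otu_table(otu[, 1:2]), "2 samples")
})

test_that("a BIOM JSON table reads to the same counts as its TSV twin", {
  skip_if_not_installed("biomformat")
  counts <- matrix(c(5L, 0L, 3L, 1L, 2L, 8L), nrow = 3)
  otu <- toy_otu(counts)
  biom_json <- jsonlite::toJSON(list(
    id = "toy", format = "1.0.0", format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "test", date = "2026-01-01",
    matrix_type = "dense", matrix_element_type = "int",
    shape = c(3L, 2L),
    rows = lapply(otu$otu_id, function(i) list(id = i, metadata = NULL)),
    columns = lapply(c("S1", "S2"), function(i) list(id = i, metadata = NULL)),
    data = lapply(seq_len(3), function(i) counts[i, ])
  ), auto_unbox = TRUE)
  path <- withr::local_tempfile(fileext = ".biom")
  writeLines(biom_json, path)
  back <- read_otu_table(path, format = "biom")
  expect_equal(otu_counts(back), otu_counts(otu))
})

test_that("metadata reading types and cross-validates a 54-sample design", {
  md <- toy_metadata(n_sites = 6, n_seasons = 3, n_reps = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(md, path, row.names = FALSE)
  back <- read_metadata(path)
  expect_equal(nrow(back), 54)
  expect_type(back$replicate, "integer")

  bad <- md
  bad$latitude[1] <- 123
  expect_error(validate_metadata(bad), "Latitude")
  expect_error(validate_metadata(md[, -2]), "site")

  otu <- toy_otu(matrix(1:4, 2), sample_ids = c("SP1_summer_1", "nope"))
  expect_error(validate_metadata(md, otu), "nope")
})

test_that("env table validation flags log-domain hazards downstream", {
  env <- tibble::tibble(sample_id = c("a", "b", "c"),
                        Chl_a = c(1, 2, 3), TP = c(0.02, 0.03, 0.04),
                        TN = c(0.5, 0.6, 0.7), SD = c(0, 2, 3),
                        COD_Mn = c(2, 2, 2))
  env <- validate_env(env)
  expect_s3_class(env, "tbl_df")
  expect_error(tli_score(env, by = "sample"), "SD")
})

test_that("composition aggregation matches direct summation", {
  # 12 phyla, k = 10: Others must equal the summed share of ranks 11-12
  set.seed(42)
  n_otu <- 24
  counts <- matrix(rpois(n_otu * 4, 30) + 1, nrow = n_otu)
  phyla <- paste0("Phylum", rep(1:12, each = 2))
  otu <- toy_otu(counts, sample_ids = c("SP1_summer_1", "SP1_summer_2",
                                        "SP2_summer_1", "SP2_summer_2"))
  tax <- tibble::tibble(otu_id = otu$otu_id, phylum = phyla)
  md <- toy_metadata(n_sites = 2, n_seasons = 1, n_reps = 2)
  res <- aggregate_composition(otu, tax, md, rank = "phylum", top_k = 10,
                               by = "site")
  sums <- tapply(res$rel_abundance, res$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # brute force: per-group share of the two globally rarest phyla
  m <- otu_counts(otu)
  rel <- sweep(m, 2, colSums(m), "/")
  overall <- tapply(rowMeans(rel), phyla, sum)
  bottom2 <- names(sort(overall))[1:2]
  for (g in c("SP1", "SP2")) {
    cols <- grepl(g, colnames(m))
    tot <- tapply(rowSums(m[, cols]), phyla, sum)
    expect_equal(
      res$rel_abundance[res$group == g & res$taxon == "Others"],
      sum(tot[bottom2]) / sum(tot))
  }

  # degenerate cases
  tax1 <- tibble::tibble(otu_id = otu$otu_id, phylum = "OnlyOne")
  r1 <- aggregate_composition(otu, tax1, md, top_k = 5, by = "site")
  expect_true(all(r1$rel_abundance[r1$taxon == "OnlyOne"] == 1))
  expect_error(aggregate_composition(otu, tax, md, rank = "genus"), "genus")
})

test_that("two phyla at 3:1 with k = 1 split 0.75 / 0.25", {
  otu <- toy_otu(matrix(c(3, 1, 3, 1), nrow = 2),
                 sample_ids = c("SP1_summer_1", "SP1_summer_2"))
  tax <- tibble::tibble(otu_id = otu$otu_id, phylum = c("A", "B"))
  md <- toy_metadata(n_sites = 1, n_seasons = 1, n_reps = 2)
  res <- aggregate_composition(otu, tax, md, top_k = 1, by = "site")
  expect_equal(res$rel_abundance[res$taxon == "A"], 0.75)
  expect_equal(res$rel_abundance[res$taxon == "Others"], 0.25)
})

test_that("network files round-trip through GraphML and GEXF is parseable", {
  edges <- tibble::tibble(otu_1 = c("a", "a", "b"), otu_2 = c("b", "c", "d"),
                          rho = c(0.9, -0.7, 0.8),
                          p_adjusted = c(0.001, 0.01, 0.02),
                          sign = c("positive", "negative", "positive"))
  g <- build_co_network(edges)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, path)
  back <- read_network(path)
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), 3)
  expect_setequal(igraph::E(back)$sign, igraph::E(g)$sign)
  expect_true("negative" %in% igraph::E(back)$sign)

  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_network(g, gexf, format = "gexf")
  doc <- xml2::read_xml(gexf)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 4)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 3)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_warning(write_network(empty, path), "empty")
})
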