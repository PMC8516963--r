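test_that("simulate_tree validates arguments and is seed-deterministic", {
  expect_error(simulate_tree(1), "n_taxa")
  expect_error(simulate_tree(4, long_multiplier = 0.5), "long_multiplier")

  two <- simulate_tree(2, seed = 1)
  expect_s3_class(two, "phylo")
  expect_length(two$tip.label, 2)

  a <- simulate_tree(8, seed = 7, long_clade_fraction = 0.25,
                     long_multiplier = 3)
  b <- simulate_tree(8, seed = 7, long_clade_fraction = 0.25,
                     long_multiplier = 3)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
})

test_that("long-branch clade scaling is a pure multiplication", {
  base <- simulate_tree(8, seed = 7, long_clade_fraction = 0.25,
                        long_multiplier = 1)
  scaled <- simulate_tree(8, seed = 7, long_clade_fraction = 0.25,
                          long_multiplier = 3)
  expect_identical(base$edge, scaled$edge)  # same topology
  ratio <- scaled$edge.length / base$edge.length
  expect_true(all(abs(ratio - 1) < 1e-12 | abs(ratio - 3) < 1e-12))
  expect_true(any(abs(ratio - 3) < 1e-12))
  # the scaled edges are exactly the flagged clade (stem + descendants)
  node <- attr(scaled, "long_clade_node")
  expect_false(is.na(node))
  expect_gt(length(attr(scaled, "long_clade_tips")), 1)
})

test_that("evolve_family honors zero-rate limits", {
  tr <- simulate_tree(6, seed = 2)
  ft <- evolve_family(tr, root_len = 50, sub_rate = 0, loss_rate = 0,
                      seed = 5)
  expect_true(all(!vapply(ft$tip_seqs, is.na, TRUE)))
  expect_true(all(unlist(ft$tip_seqs) == ft$root_seq))

  ft2 <- evolve_family(tr, root_len = 50, sub_rate = 0.5, loss_rate = 0,
                       seed = 5)
  expect_true(all(!vapply(ft2$tip_seqs, is.na, TRUE)))
  expect_length(ft2$loss_branches, 0)
})

test_that("loss fraction matches the closed form on a two-tip tree", {
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  n <- 10000
  lost <- logical(2 * n)
  for (i in seq_len(n)) {
    ft <- evolve_family(tr, root_len = 5, sub_rate = 0, loss_rate = 0.5,
                        seed = i)
    lost[2 * i - 1] <- is.na(ft$tip_seqs[[1]])
    lost[2 * i] <- is.na(ft$tip_seqs[[2]])
  }
  p <- 1 - exp(-0.5)
  se <- sqrt(p * (1 - p) / (2 * n))
  expect_lt(abs(mean(lost) - p), 3 * se)
})

test_that("losses are Dollo-consistent and form an antichain", {
  for (s in 1:15) {
    tr <- simulate_tree(10, seed = s)
    ft <- evolve_family(tr, root_len = 30, sub_rate = 0.2, loss_rate = 0.4,
                        seed = 100 + s)
    ntip <- length(tr$tip.label)
    for (lb in ft$loss_branches) {
      below <- c(lb, orthotrace:::node_descendants(tr, lb))
      tips_below <- tr$tip.label[below[below <= ntip]]
      expect_true(all(vapply(ft$tip_seqs[tips_below], is.na, TRUE)))
      # no other loss branch is a descendant of this one
      expect_length(intersect(setdiff(ft$loss_branches, lb),
                              below), 0)
    }
    # a tip is absent iff some loss branch lies on its root path
    lost_tips <- names(ft$tip_seqs)[vapply(ft$tip_seqs, is.na, TRUE)]
    covered <- unlist(lapply(ft$loss_branches, function(lb) {
      below <- c(lb, orthotrace:::node_descendants(tr, lb))
      tr$tip.label[below[below <= ntip]]
    }))
    if (is.null(covered)) covered <- character(0)
    expect_setequal(lost_tips, covered)
  }
})

test_that("emitted genomes embed genes that translate back exactly", {
  tr <- simulate_tree(4, seed = 3)
  truths <- lapply(1:3, function(i)
    evolve_family(tr, root_len = 60, sub_rate = 0.2, loss_rate = 0.3,
                  seed = i, family = paste0("f", i)))
  em <- emit_genome_and_proteome(truths, intergenic_len = 50,
                                 hide_fraction = 0, seed = 11)
  expect_true(all(!em$registry$hidden))
  for (r in seq_len(nrow(em$registry))) {
    row <- em$registry[r, ]
    cds <- substr(em$genomes[[row$taxon]], row$start, row$end)
    if (row$strand == "-") cds <- oracle_revcomp(cds)
    ncod <- nchar(cds) / 3
    aa <- paste(vapply(seq_len(ncod), function(i)
      oracle_translate_codon(substr(cds, 3 * i - 2, 3 * i)), ""),
      collapse = "")
    fam <- which(vapply(truths, function(t) t$family == row$family, TRUE))
    expect_identical(aa, truths[[fam]]$tip_seqs[[row$taxon]])
    expect_false(grepl("\\*", aa))  # no in-frame stops inside genes
  }
})

test_that("hide_fraction extremes control the proteome", {
  tr <- simulate_tree(4, seed = 3)
  truths <- lapply(1:3, function(i)
    evolve_family(tr, root_len = 40, sub_rate = 0.1, loss_rate = 0,
                  seed = i, family = paste0("f", i)))
  all_in <- emit_genome_and_proteome(truths, hide_fraction = 0, seed = 1)
  expect_equal(sum(lengths(all_in$proteomes)), nrow(all_in$registry))

  none_in <- emit_genome_and_proteome(truths, hide_fraction = 1, seed = 1)
  expect_equal(sum(lengths(none_in$proteomes)), 0)
  expect_true(all(none_in$registry$hidden))
})

test_that("pileup simulation matches its contract", {
  clean <- simulate_pileup(1, 2000, 25, error_rate = 0, seed = 4)
  hc <- call_het_sites(clean, min_cov = 1, min_alt_reads = 1)
  expect_equal(sum(hc$n2 > 0), 0)  # one observed base per site

  n <- 100000
  dip <- simulate_pileup(2, n, 30, error_rate = 0, het_density = 0.01,
                         seed = 5)
  frac <- mean(attr(dip, "truth_biallelic"))
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(frac - 0.01), 3 * se)

  again <- simulate_pileup(2, 100, 30, 0.01, 0.05, seed = 9)
  expect_identical(simulate_pileup(2, 100, 30, 0.01, 0.05, seed = 9),
                   again)
})

test_that("k-mer sets follow construction and determinism", {
  g <- random_dna(500, seed = 6)
  expect_error(sample_kmer_sets("ACGT", k = 21), "shortest")

  ks <- sample_kmer_sets(g, k = 15, read_cov = 20, dropout = 0, seed = 2)
  solid <- ks$read_kmers$kmer[ks$read_kmers$count >= 4]
  expect_true(all(solid %in% ks$assembly_kmers))

  ks2 <- sample_kmer_sets(g, k = 15, read_cov = 20, dropout = 0, seed = 2)
  expect_identical(ks, ks2)
  ks17 <- sample_kmer_sets(g, k = 17, read_cov = 20, dropout = 0, seed = 2)
  expect_false(identical(ks$assembly_kmers, ks17$assembly_kmers))

  # canonical k-mers are strand-symmetric
  expect_setequal(unique(canonical_kmers(g, 15)),
                  unique(canonical_kmers(oracle_revcomp(g), 15)))
})
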