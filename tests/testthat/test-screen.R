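test_that("six-frame translation handles single codons and strands", {
  fw <- six_frame_translate("ATG", 1)
  expect_true(any(fw$frame == 1 & fw$aa == "M"))
  rv <- six_frame_translate("CAT", 1)
  expect_true(any(rv$frame == -1 & rv$aa == "M"))
  expect_error(six_frame_translate("ACGU", 1), "invalid-input")
  expect_error(six_frame_translate("ATG", 0), "min_len")
})

test_that("six-frame segments match an independent genetic-code oracle", {
  for (s in 1:4) {
    dna <- random_dna(3000, seed = 500 + s)
    got <- six_frame_translate(dna, min_len = 5)
    got <- got[order(got$frame, got$start),
               c("frame", "start", "end", "aa")]
    rownames(got) <- NULL
    want <- oracle_six_frame(dna, min_len = 5)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("translated segments round-trip through their coordinates", {
  dna <- random_dna(600, seed = 11)
  segs <- six_frame_translate(dna, min_len = 3)
  for (i in seq_len(nrow(segs))) {
    piece <- substr(dna, segs$start[i], segs$end[i])
    if (segs$frame[i] < 0) piece <- oracle_revcomp(piece)
    ncod <- nchar(piece) / 3
    aa <- paste(vapply(seq_len(ncod), function(k)
      oracle_translate_codon(substr(piece, 3 * k - 2, 3 * k)), ""),
      collapse = "")
    expect_identical(aa, segs$aa[i])
  }
})

make_simple_family <- function(seed = 1, len = 120) {
  root <- random_aa(len, seed = seed)
  msa <- seed_msa_from_root(root, n = 4, divergence = 0.05,
                            seed = seed + 1)
  list(fam = calibrate_family(msa, family = "famX", seed = seed),
       root = root)
}

test_that("verify_absence walks the cascade tiers", {
  sf <- make_simple_family(seed = 21)

  hit <- verify_absence(sf$fam, proteome = c(p1 = sf$root), genome = NULL,
                        taxon = "tx")
  expect_equal(hit$state, "present")
  expect_equal(hit$tier, "proteome")
  expect_true(hit$genome_unchecked)

  none <- verify_absence(sf$fam, proteome = character(0), genome = NULL,
                         taxon = "tx")
  expect_equal(none$state, "absent")
  expect_equal(none$tier, "none")

  # gene embedded in the genome but missing from the proteome
  cds <- orthotrace:::reverse_translate(sf$root)
  genome <- c(c1 = paste0(random_dna(90, 1), cds, random_dna(90, 2)))
  rescue <- verify_absence(sf$fam, proteome = character(0),
                           genome = genome, taxon = "tx")
  expect_equal(rescue$state, "present_genome_only")
  expect_equal(rescue$tier, "six-frame")
  expect_false(rescue$genome_unchecked)
  expect_equal(rescue$strand, "+")
  # reported interval lies inside the embedded gene
  expect_gte(rescue$start, 91)
  expect_lte(rescue$end, 90 + nchar(cds))
})

test_that("tier-1 paralog count reflects qualifying proteome sequences", {
  sf <- make_simple_family(seed = 22)
  two <- verify_absence(sf$fam,
                        proteome = c(a = sf$root, b = sf$root,
                                     junk = random_aa(100, 9)),
                        genome = NULL, taxon = "tx")
  expect_equal(two$state, "present")
  expect_equal(two$paralogs, 2L)
})

test_that("tier-2 paralog count merges overlapping genome intervals", {
  sf <- make_simple_family(seed = 23)
  cds <- orthotrace:::reverse_translate(sf$root)
  genome <- c(c1 = paste0(random_dna(60, 3), cds, random_dna(120, 4),
                          cds, random_dna(60, 5)))
  r <- verify_absence(sf$fam, proteome = character(0), genome = genome,
                      taxon = "tx")
  expect_equal(r$state, "present_genome_only")
  expect_equal(r$paralogs, 2L)
})

test_that("relaxed domain tier rescues a domain-only match", {
  # fixture: the conserved domain diverged far enough that the
  # full-length profile misses at the strict threshold, while the
  # domain sub-profile (calibrated on its own, shorter null) still
  # hits at the relaxed 1e-3 threshold
  root <- random_aa(150, seed = 35)
  msa <- seed_msa_from_root(root, n = 4, divergence = 0.05, seed = 36)
  domain <- substr(root, 51, 100)
  dom_msa <- seed_msa_from_root(domain, n = 4, divergence = 0.05,
                                seed = 37)
  fam <- calibrate_family(msa, family = "famD",
                          domain_msas = list(dom = dom_msa), seed = 38)

  set.seed(39)
  dch <- strsplit(domain, "")[[1]]
  hit <- which(runif(length(dch)) < 0.5)
  for (j in hit) dch[j] <- sample(setdiff(AA20, dch[j]), 1)
  set.seed(39 + 1000)
  target <- paste0(paste(sample(AA20, 60, TRUE), collapse = ""),
                   paste(dch, collapse = ""),
                   paste(sample(AA20, 60, TRUE), collapse = ""))

  call <- verify_absence(fam, proteome = c(t1 = target), genome = NULL,
                         taxon = "tx")
  expect_equal(call$tier, "domain")
  expect_equal(call$state, "present")
})

test_that("screen_all recovers the simulated truth table", {
  tr <- simulate_tree(5, seed = 8)
  truths <- lapply(1:5, function(i)
    evolve_family(tr, root_len = 90, sub_rate = 0.25, loss_rate = 0.25,
                  seed = 300 + i, family = sprintf("f%02d", i)))
  em <- emit_genome_and_proteome(truths, intergenic_len = 100,
                                 hide_fraction = 0.25, seed = 301)
  fams <- lapply(truths, function(t)
    calibrate_family(seed_msa_from_root(t$root_seq, n = 4,
                                        divergence = 0.08,
                                        seed = 302),
                     family = t$family, seed = 303))
  names(fams) <- vapply(truths, function(t) t$family, "")
  taxa_data <- lapply(tr$tip.label, function(tx)
    list(proteome = em$proteomes[[tx]],
         genome = setNames(em$genomes[tx], paste0(tx, "_c1"))))
  names(taxa_data) <- tr$tip.label

  calls <- screen_all(fams, taxa_data)
  expect_equal(nrow(calls), 5 * 5)

  truth <- do.call(rbind, lapply(truths, function(t)
    data.frame(family = t$family, taxon = names(t$tip_seqs),
               present = !vapply(t$tip_seqs, is.na, TRUE),
               stringsAsFactors = FALSE)))
  m <- merge(calls, truth)
  expect_true(all((m$state != "absent") == m$present))

  # hidden-but-embedded genes surface as genome-only detections
  hid <- merge(calls, em$registry[em$registry$hidden,
                                  c("family", "taxon")])
  expect_true(all(hid$state == "present_genome_only"))
  expect_true(all(hid$tier == "six-frame"))

  # loss_rate = 0 and hide_fraction = 0: everything present via proteome
  truths0 <- lapply(1:3, function(i)
    evolve_family(tr, root_len = 90, sub_rate = 0.25, loss_rate = 0,
                  seed = 400 + i, family = sprintf("g%02d", i)))
  em0 <- emit_genome_and_proteome(truths0, hide_fraction = 0, seed = 401)
  fams0 <- lapply(truths0, function(t)
    calibrate_family(seed_msa_from_root(t$root_seq, n = 4,
                                        divergence = 0.08, seed = 402),
                     family = t$family, seed = 403))
  names(fams0) <- vapply(truths0, function(t) t$family, "")
  taxa0 <- lapply(tr$tip.label, function(tx)
    list(proteome = em0$proteomes[[tx]],
         genome = setNames(em0$genomes[tx], paste0(tx, "_c1"))))
  names(taxa0) <- tr$tip.label
  calls0 <- screen_all(fams0, taxa0)
  expect_true(all(calls0$state == "present"))
  expect_true(all(calls0$tier == "proteome"))
})
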