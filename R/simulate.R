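## Synthetic genome/proteome evolution: the ground-truth generator for
## end-to-end validation of the search, screening and loss-mapping code.

#' Simulate a rooted species tree with an optional long-branch clade
#'
#' Generates a random rooted binary tree (birth-style topology with
#' exponential branch lengths, expected substitutions/site) and, when
#' `long_clade_fraction > 0`, selects the internal clade whose tip count
#' is closest to `long_clade_fraction * n_taxa` and multiplies every
#' branch inside it (stem included) by `long_multiplier` — emulating a
#' fast-evolving lineage nested in the tree.
#'
#' @param n_taxa Number of tips (>= 2). Tip labels are `t1..tn`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param long_clade_fraction Fraction of taxa in the long-branch clade
#'   (0 disables the clade).
#' @param long_multiplier Branch-length multiplier for the clade (>= 1).
#' @param mean_branch Mean branch length before scaling (default 0.15).
#' @return An `ape::phylo` tree with attributes `long_clade_node`
#'   (internal node number or `NA`) and `long_clade_tips` (tip labels).
#' @export
simulate_tree <- function(n_taxa, seed = 1, long_clade_fraction = 0,
                          long_multiplier = 1, mean_branch = 0.15) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  if (long_multiplier < 1) stop("long_multiplier must be >= 1", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = TRUE,
                   br = function(n) rexp(n, rate = 1 / mean_branch))
  tr$tip.label <- paste0("t", seq_len(n_taxa))

  long_node <- NA_integer_; long_tips <- character(0)
  if (long_clade_fraction > 0 && n_taxa >= 3) {
    target <- max(2, round(long_clade_fraction * n_taxa))
    internal <- (n_taxa + 2):(n_taxa + tr$Nnode)  # exclude root
    if (length(internal) > 0) {
      sizes <- vapply(internal, function(nd)
        length(tip_descendants(tr, nd)), 1L)
      long_node <- internal[which.min(abs(sizes - target))]
      desc <- node_descendants(tr, long_node)
      scale_edges <- which(tr$edge[, 2] %in% c(long_node, desc))
      tr$edge.length[scale_edges] <- tr$edge.length[scale_edges] *
        long_multiplier
      long_tips <- tr$tip.label[intersect(desc, seq_len(n_taxa))]
    }
  }
  attr(tr, "long_clade_node") <- long_node
  attr(tr, "long_clade_tips") <- long_tips
  tr
}

## All descendant node numbers (tips + internals) of `node`, excluding it.
node_descendants <- function(tree, node) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids); stack <- c(stack, kids)
  }
  out
}

tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  d <- node_descendants(tree, node)
  length(d[d <= n])
}

#' Evolve a protein family along a species tree with Dollo losses
#'
#' The ancestral sequence (length `root_len`, drawn from `background`)
#' evolves down the tree. Along a branch of length `t` the family is
#' lost with probability `1 - exp(-loss_rate * t)`; loss is irreversible
#' (Dollo), so all descendant tips are absent. If retained, each site is
#' substituted with probability `1 - exp(-sub_rate * t)`; a substitution
#' replaces the residue by a draw from the background distribution
#' restricted to the 19 other residues, so the realized substitution
#' fraction matches the closed form.
#'
#' @param tree `phylo` species tree from [simulate_tree()].
#' @param root_len Ancestral sequence length (> 0).
#' @param sub_rate Substitution events per site per unit branch length.
#' @param loss_rate Loss events per unit branch length.
#' @param seed Integer seed.
#' @param family Family id.
#' @param background Amino-acid frequencies for root and replacements.
#' @return Object of class `family_truth`: `family`, `root_seq`,
#'   `tip_seqs` (named list, `NA` for absent tips), `loss_branches`
#'   (child-node numbers of true loss branches, an antichain),
#'   `in_proteome` (named logical, set by [emit_genome_and_proteome()]).
#' @export
evolve_family <- function(tree, root_len = 120, sub_rate = 0.3,
                          loss_rate = 0, seed = 1, family = "fam1",
                          background = uniform_background()) {
  if (root_len <= 0) stop("root_len must be > 0", call. = FALSE)
  if (sub_rate < 0 || loss_rate < 0) stop("rates must be >= 0", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  root_seq <- aa_random(root_len, background)
  seqs <- list(); seqs[[as.character(root)]] <- root_seq
  lost <- logical(max(tree$edge))
  loss_branches <- integer(0)

  ## preorder over edges (ape trees from rtree are in preorder already,
  ## but enforce it)
  ord <- order(match(tree$edge[, 1], c(root, node_descendants(tree, root))))
  for (k in ord) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    t_br <- tree$edge.length[k]
    if (lost[par]) { lost[child] <- TRUE; next }
    if (loss_rate > 0 && runif(1) < 1 - exp(-loss_rate * t_br)) {
      lost[child] <- TRUE
      loss_branches <- c(loss_branches, child)
      next
    }
    parent_seq <- seqs[[as.character(par)]]
    chars <- strsplit(parent_seq, "", fixed = TRUE)[[1]]
    if (sub_rate > 0) {
      p_sub <- 1 - exp(-sub_rate * t_br)
      hit <- which(runif(length(chars)) < p_sub)
      for (i in hit) {
        bg <- background
        bg[chars[i]] <- 0
        chars[i] <- sample(AA_ALPHABET, 1, prob = bg)
      }
    }
    seqs[[as.character(child)]] <- paste(chars, collapse = "")
  }

  tip_seqs <- setNames(vector("list", ntip), tree$tip.label)
  for (i in seq_len(ntip)) {
    tip_seqs[[i]] <- if (lost[i]) NA_character_ else seqs[[as.character(i)]]
  }
  structure(list(family = family, root_seq = root_seq, tip_seqs = tip_seqs,
                 loss_branches = loss_branches,
                 in_proteome = setNames(!vapply(tip_seqs, is.na, TRUE),
                                        tree$tip.label)),
            class = "family_truth")
}

## codons per amino acid from the standard genetic code (table 1)
codons_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

## Reverse-translate a protein with uniform synonymous codon choice.
reverse_translate <- function(protein, codon_table = codons_for_aa()) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(a) {
    cods <- codon_table[[a]]
    if (is.null(cods)) stop("no codon for residue ", a, call. = FALSE)
    cods[sample.int(length(cods), 1)]
  }, ""), collapse = "")
}

#' Simulate a divergence bridge for iterative-search validation
#'
#' Constructs the three-sequence chain that motivates iterative
#' taxa-enrichment: a seed alignment of near-identical homologs of an
#' ancestral protein, a mid-divergent homolog (per-site substitution
#' probability `d_mid`), and a far-divergent homolog that agrees with
#' the mid homolog exactly at the positions where the mid homolog
#' diverged from the ancestor and is randomized elsewhere. The far
#' homolog is therefore near-random to a profile built from the seeds
#' alone, but strongly matched by a profile enriched with the mid
#' homolog — it can only be recovered through the bridge.
#'
#' @param root_len Ancestral protein length.
#' @param n_seeds Rows in the seed alignment.
#' @param seed_divergence Per-site substitution probability of each
#'   seed row (default 0.05).
#' @param d_mid Per-site substitution probability of the mid homolog
#'   (default 0.4).
#' @param keep_root_frac Fraction of ancestral-consensus positions at
#'   which the far homolog retains the ancestral residue (default
#'   0.35). Kept sparse, these matches stay insignificant against the
#'   seed-only profile (the intervening randomized positions dominate)
#'   but add to the enriched-profile score.
#' @param seed Integer seed.
#' @param background Replacement distribution.
#' @return List with `seed_msa` (named character), `mid`, `far`.
#' @export
simulate_bridge_family <- function(root_len = 250, n_seeds = 4,
                                   seed_divergence = 0.05, d_mid = 0.4,
                                   keep_root_frac = 0.35, seed = 1,
                                   background = uniform_background()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  root <- aa_random(root_len, background)
  perturb <- function(s, d) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < d)
    for (j in hit) {
      bg <- background; bg[ch[j]] <- 0
      ch[j] <- sample(AA_ALPHABET, 1, prob = bg)
    }
    paste(ch, collapse = "")
  }
  seed_msa <- setNames(vapply(seq_len(n_seeds), function(i)
    perturb(root, seed_divergence), ""), paste0("seed", seq_len(n_seeds)))
  mid <- perturb(root, d_mid)
  rc <- strsplit(root, "", fixed = TRUE)[[1]]
  mc <- strsplit(mid, "", fixed = TRUE)[[1]]
  fc <- character(length(rc))
  ## ancestral residues kept by the far homolog are spaced evenly over
  ## the consensus positions, so their contribution to any local
  ## alignment window is bounded (no lucky clusters)
  cons <- which(mc == rc)
  keep <- integer(0)
  if (keep_root_frac > 0 && length(cons) > 0) {
    stride <- max(1L, round(1 / keep_root_frac))
    keep <- cons[seq(1, length(cons), by = stride)]
  }
  for (i in seq_along(rc)) {
    if (mc[i] != rc[i]) fc[i] <- mc[i]
    else if (i %in% keep) fc[i] <- rc[i]
    else {
      bg <- background; bg[rc[i]] <- 0
      fc[i] <- sample(AA_ALPHABET, 1, prob = bg)
    }
  }
  list(seed_msa = seed_msa, mid = mid, far = paste(fc, collapse = ""))
}

#' Emit a genome/proteome pair with controlled annotation failures
#'
#' Each present tip protein is reverse-translated (standard genetic
#' code, uniform synonymous codon choice) and embedded on a random
#' strand of a single synthetic contig per taxon, separated by random
#' intergenic spacers. A `hide_fraction` subset of embedded genes is
#' omitted from the proteome — emulating annotation failure — and
#' recorded in the hidden-gene registry, so six-frame rescue can be
#' scored against ground truth. Embedded coding intervals contain no
#' in-frame stop codons.
#'
#' @param truths List of `family_truth` objects over the same taxa.
#' @param intergenic_len Spacer length between genes (bp).
#' @param hide_fraction Fraction of present genes hidden from the
#'   proteome, in `[0, 1]`; the hidden subset is drawn over all
#'   present genes across taxa.
#' @param seed Integer seed.
#' @return List with `genomes` (named character, one contig per taxon),
#'   `proteomes` (named list: taxon -> named character vector of
#'   proteins), `registry` (data frame: family, taxon, state, hidden,
#'   contig, start, end, strand — 1-based inclusive coordinates of the
#'   coding interval on the forward strand).
#' @export
emit_genome_and_proteome <- function(truths, intergenic_len = 200,
                                     hide_fraction = 0, seed = 1) {
  if (hide_fraction < 0 || hide_fraction > 1)
    stop("hide_fraction must be in [0, 1]", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  codon_table <- codons_for_aa()

  taxa <- names(truths[[1]]$tip_seqs)
  genomes <- setNames(character(length(taxa)), taxa)
  proteomes <- setNames(vector("list", length(taxa)), taxa)
  reg <- list()

  ## choose hidden (family, taxon) pairs among all present genes
  present <- do.call(rbind, lapply(truths, function(tr)
    data.frame(family = tr$family, taxon = taxa,
               present = !vapply(tr$tip_seqs, is.na, TRUE),
               stringsAsFactors = FALSE)))
  idx_present <- which(present$present)
  n_hide <- round(hide_fraction * length(idx_present))
  hidden_idx <- if (n_hide > 0) sample(idx_present, n_hide) else integer(0)
  key <- function(f, t) paste0(f, "\r", t)
  hidden_keys <- key(present$family[hidden_idx], present$taxon[hidden_idx])

  for (tx in taxa) {
    segs <- character(0)
    pos <- 0L
    prot <- character(0)
    spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
    for (tr in truths) {
      aa <- tr$tip_seqs[[tx]]
      if (is.na(aa)) next
      sp <- spacer(intergenic_len)
      cds <- reverse_translate(aa, codon_table)
      strand <- sample(c("+", "-"), 1)
      embedded <- if (strand == "+") cds else revcomp(cds)
      segs <- c(segs, sp, embedded)
      start <- pos + intergenic_len + 1L
      end <- start + nchar(cds) - 1L
      pos <- end
      hid <- key(tr$family, tx) %in% hidden_keys
      if (!hid) prot[paste0(tr$family, "_", tx)] <- aa
      reg[[length(reg) + 1L]] <- data.frame(
        family = tr$family, taxon = tx, state = "present",
        hidden = hid, contig = paste0(tx, "_c1"),
        start = start, end = end, strand = strand,
        stringsAsFactors = FALSE)
    }
    segs <- c(segs, spacer(intergenic_len))
    genomes[tx] <- paste(segs, collapse = "")
    proteomes[[tx]] <- prot
  }

  registry <- if (length(reg)) do.call(rbind, reg) else
    data.frame(family = character(0), taxon = character(0),
               state = character(0), hidden = logical(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  list(genomes = genomes, proteomes = proteomes, registry = registry)
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Simulate a per-site base-count pileup
#'
#' Per-site read depth is Poisson(`mean_cov`). For `ploidy = 2`, a
#' `het_density` fraction of sites is truly biallelic: each read draws
#' one of two alleles with probability 1/2. Sequencing errors replace a
#' read's base with a uniformly chosen different base at rate
#' `error_rate`.
#'
#' @param ploidy 1 or 2.
#' @param n_sites Number of sites.
#' @param mean_cov Mean coverage (> 0).
#' @param error_rate Per-read error probability.
#' @param het_density Fraction of truly heterozygous sites (diploid only).
#' @param seed Integer seed.
#' @return Data frame with columns `site`, `A`, `C`, `G`, `T` and a
#'   logical attribute `truth_biallelic` flagging truly biallelic sites.
#' @export
simulate_pileup <- function(ploidy = 1, n_sites = 1000, mean_cov = 30,
                            error_rate = 0, het_density = 0, seed = 1) {
  stopifnot(ploidy %in% c(1, 2), mean_cov > 0,
            error_rate >= 0, error_rate <= 1,
            het_density >= 0, het_density <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cov <- rpois(n_sites, mean_cov)
  ref <- sample.int(4, n_sites, replace = TRUE)
  is_het <- if (ploidy == 2) runif(n_sites) < het_density else
    rep(FALSE, n_sites)
  alt <- ((ref - 1L + sample.int(3, n_sites, replace = TRUE)) %% 4L) + 1L

  ## per-site multinomial base probabilities: a read draws an allele
  ## (ref, or ref/alt at 1/2 each when truly biallelic), then an error
  ## moves it to a uniformly chosen different base
  e <- error_rate
  probs <- matrix(e / 3, n_sites, 4)
  w_ref <- ifelse(is_het, 0.5, 1)
  for (b in 1:4) {
    pb <- e / 3 +
      ifelse(ref == b, w_ref * (1 - e - e / 3), 0) +
      ifelse(is_het & alt == b, 0.5 * (1 - e - e / 3), 0)
    probs[, b] <- pb
  }
  ## exact multinomial via sequential binomials, vectorized over sites
  counts <- matrix(0L, n_sites, 4, dimnames = list(NULL, bases))
  remaining <- cov
  pleft <- rep(1, n_sites)
  for (b in 1:4) {
    p <- ifelse(pleft > 0, pmin(probs[, b] / pleft, 1), 0)
    x <- rbinom(n_sites, remaining, p)
    counts[, b] <- x
    remaining <- remaining - x
    pleft <- pleft - probs[, b]
  }
  out <- data.frame(site = seq_len(n_sites), counts)
  attr(out, "truth_biallelic") <- is_het
  out
}

## all canonical k-mers of a set of sequences (character vector)
#' Canonical k-mers of a nucleotide sequence set
#'
#' A canonical k-mer is the lexicographic minimum of a k-mer and its
#' reverse complement.
#'
#' @param seqs Character vector of DNA sequences.
#' @param k k-mer size.
#' @return Character vector of canonical k-mers (one per position,
#'   duplicates retained; use `unique()` for the set).
#' @export
canonical_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    if (k > L) stop("k longer than sequence", call. = FALSE)
    starts <- seq_len(L - k + 1L)
    fw <- substring(s, starts, starts + k - 1L)
    rc_full <- revcomp(s)
    rstarts <- L - (starts + k - 1L) + 1L
    rv <- substring(rc_full, rstarts, rstarts + k - 1L)
    out <- c(out, pmin(fw, rv))
  }
  out
}

#' Sample assembly and read k-mer sets from a genome
#'
#' The read k-mer table counts canonical k-mers of the genome under
#' Poisson(`read_cov`) sequencing of every position. The assembly k-mer
#' set is the canonical k-mer set of the genome with a `dropout`
#' fraction of positions removed — emulating regions missing from the
#' assembly — so the downstream k-mer completeness of a dropout-`d`
#' assembly is close to `100 * (1 - d)` percent.
#'
#' @param genome Character vector of contig sequences.
#' @param k k-mer size (>= 11 recommended).
#' @param read_cov Mean per-position read coverage.
#' @param dropout Fraction of genome k-mer positions absent from the
#'   assembly, in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `assembly_kmers` (character set) and `read_kmers`
#'   (data frame `kmer`, `count`).
#' @export
sample_kmer_sets <- function(genome, k = 21, read_cov = 30, dropout = 0,
                             seed = 1) {
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0,1]",
                                       call. = FALSE)
  if (k > min(nchar(genome))) stop("k longer than shortest sequence",
                                   call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  all_kmers <- canonical_kmers(genome, k)
  n <- length(all_kmers)

  keep <- runif(n) >= dropout
  assembly <- unique(all_kmers[keep])

  depth <- rpois(n, read_cov)
  tab <- tapply(depth, all_kmers, sum)
  read_kmers <- data.frame(kmer = names(tab), count = as.integer(tab),
                           stringsAsFactors = FALSE)
  read_kmers <- read_kmers[read_kmers$count > 0, , drop = FALSE]
  rownames(read_kmers) <- NULL
  list(assembly_kmers = assembly, read_kmers = read_kmers)
}
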