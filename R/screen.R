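## Tiered absence-verification cascade: proteome search, six-frame
## translated genome rescue, relaxed domain-level screening.

#' Six-frame conceptual translation of a nucleotide sequence
#'
#' Translates all three frames of both strands with the standard
#' genetic code. Translation segments are split at stop codons and at
#' all-`N` codons (runs of ambiguity); codons containing an `N`
#' translate to `X`. Segments shorter than `min_len` are discarded.
#' Internal coordinates are 0-based half-open; the returned intervals
#' are 1-based inclusive on the forward strand, so that extracting the
#' interval, reverse-complementing when `frame < 0`, and translating
#' reproduces the amino-acid sequence.
#'
#' @param dna Nucleotide sequence over `A,C,G,T,N` (single string).
#' @param min_len Minimum segment length in residues (>= 1).
#' @param contig Contig id recorded on segments.
#' @return Data frame with columns `contig`, `frame` (+1,+2,+3,-1,-2,-3),
#'   `start`, `end` (forward-strand, 1-based inclusive), `aa`.
#' @export
six_frame_translate <- function(dna, min_len = 1, contig = "contig") {
  if (min_len < 1) stop("min_len must be >= 1", call. = FALSE)
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("invalid-input: sequence contains non-ACGTN characters",
         call. = FALSE)
  L <- nchar(dna)
  out <- list()
  strands <- list(`+` = dna, `-` = if (L > 0) revcomp(dna) else "")
  for (sgn in c(1L, -1L)) {
    s <- strands[[if (sgn > 0) "+" else "-"]]
    for (off in 0:2) {
      ncod <- (L - off) %/% 3L
      if (ncod < 1) next
      sub <- substr(s, off + 1L, off + 3L * ncod)
      codons <- substring(sub, seq(1, 3 * ncod, 3), seq(3, 3 * ncod, 3))
      aa <- translate_codons(codons)
      breaker <- aa == "*" | codons == "NNN"
      runs <- split(seq_len(ncod), cumsum(c(TRUE, breaker[-ncod])) )
      for (r in runs) {
        r <- r[!breaker[r]]
        if (length(r) < min_len) next
        pep <- paste(aa[r], collapse = "")
        ## codon positions (on this strand's coordinates, 1-based)
        s1 <- off + 3L * (r[1] - 1L) + 1L
        s2 <- off + 3L * r[length(r)]
        if (sgn > 0) { f_start <- s1; f_end <- s2 }
        else { f_start <- L - s2 + 1L; f_end <- L - s1 + 1L }
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, frame = sgn * (off + 1L),
          start = f_start, end = f_end, aa = pep,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Standard-code codon translation; codons with N give X.
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

## Six-frame segments for a named genome (vector of contigs).
genome_segments <- function(genome, min_len = 30) {
  segs <- lapply(names(genome) %||% paste0("c", seq_along(genome)),
                 function(nm) six_frame_translate(genome[[nm]], min_len, nm))
  if (is.null(names(genome))) names(genome) <- paste0("c", seq_along(genome))
  do.call(rbind, segs)
}

default_screen_config <- function() {
  list(inclusion_E = 1e-5, domain_E = 1e-3, min_seg_len = 30,
       gap_open = 3.5, gap_extend = 0.3, overlap_merge = 0.25)
}

best_hit <- function(profile, fit, seqs, db_residues, gap_open, gap_extend) {
  if (length(seqs) == 0 || db_residues == 0)
    return(list(target = NA_character_, score = -Inf, evalue = Inf,
                scores = numeric(0), evalues = numeric(0)))
  sc <- score_many(profile, seqs, gap_open, gap_extend)
  ev <- evalue(fit, sc, db_residues)
  i <- which.min(ev)
  list(target = (names(seqs) %||% as.character(seq_along(seqs)))[i],
       score = sc[i], evalue = ev[i], scores = sc, evalues = ev)
}

#' Tiered absence verification for one family in one taxon
#'
#' Runs the absence-verification cascade:
#' \describe{
#'   \item{Tier 1 (proteome)}{full-family profile vs. the predicted
#'     proteome at the family inclusion threshold; a hit calls
#'     `present` with tier `proteome`.}
#'   \item{Tier 2 (six-frame)}{full-family profile vs. stop-free
#'     six-frame translation segments of the genome at the same
#'     threshold; a hit calls `present_genome_only` with tier
#'     `six-frame` (the gene exists but was not annotated).}
#'   \item{Tier 3 (domain)}{each domain sub-profile vs. proteome and
#'     segments at the relaxed threshold (default `1e-3`); a proteome
#'     hit calls `present`, a genome-only hit `present_genome_only`,
#'     both with tier `domain`.}
#' }
#' Otherwise the family is called `absent` with tier `none`. When no
#' genome is supplied the call is made on the proteome alone and
#' flagged `genome_unchecked`.
#'
#' @param family List with elements `profile` (`profile_matrix`), `fit`
#'   (`calibration_fit`), optional `domains` (list of
#'   `list(profile=, fit=)`), and `family` (id).
#' @param proteome Named character vector of proteins (may be empty).
#' @param genome Named character vector of contigs, or `NULL`.
#' @param config List of thresholds; see `default_screen_config()`.
#' @param taxon Taxon id recorded on the call.
#' @param segments Optional precomputed six-frame segment table (from
#'   `genome_segments()`), to avoid retranslating per family.
#' @return One-row data frame: `family`, `taxon`, `state`
#'   (`present`/`present_genome_only`/`absent`), `tier` (`proteome`/
#'   `six-frame`/`domain`/`none`), `best_target`, `start`, `end`,
#'   `strand` (genome hits; NA otherwise), `bitscore`, `evalue`,
#'   `paralogs`, `genome_unchecked`.
#' @export
verify_absence <- function(family, proteome, genome, config = list(),
                           taxon = NA_character_, segments = NULL) {
  cfg <- utils::modifyList(default_screen_config(), config)
  fam_id <- family$family %||% family$profile$family
  prot_res <- sum(nchar(proteome))
  genome_unchecked <- is.null(genome) || length(genome) == 0

  call_row <- function(state, tier, target = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_, score = NA_real_,
                       ev = NA_real_, paralogs = 0L) {
    data.frame(family = fam_id, taxon = taxon, state = state, tier = tier,
               best_target = target, start = start, end = end,
               strand = strand, bitscore = score, evalue = ev,
               paralogs = paralogs, genome_unchecked = genome_unchecked,
               stringsAsFactors = FALSE)
  }

  ## Tier 1: proteome at the family threshold
  t1 <- best_hit(family$profile, family$fit, proteome, prot_res,
                 cfg$gap_open, cfg$gap_extend)
  if (is.finite(t1$evalue) && t1$evalue <= cfg$inclusion_E) {
    paralogs <- sum(t1$evalues <= cfg$inclusion_E)
    return(call_row("present", "proteome", t1$target, score = t1$score,
                    ev = t1$evalue, paralogs = as.integer(paralogs)))
  }

  ## Tier 2: six-frame segments at the family threshold
  if (!genome_unchecked) {
    if (is.null(segments)) segments <- genome_segments(genome, cfg$min_seg_len)
    seg_ids <- sprintf("%s:%+d:%d-%d", segments$contig, segments$frame,
                       segments$start, segments$end)
    seg_seqs <- setNames(segments$aa, seg_ids)
    seg_res <- sum(nchar(seg_seqs))
    t2 <- best_hit(family$profile, family$fit, seg_seqs, seg_res,
                   cfg$gap_open, cfg$gap_extend)
    if (is.finite(t2$evalue) && t2$evalue <= cfg$inclusion_E) {
      i <- which(seg_ids == t2$target)[1]
      gcoord <- segment_hit_coords(family$profile, segments[i, ],
                                   cfg$gap_open, cfg$gap_extend)
      paralogs <- count_paralogs(segments, t2$evalues, t2$scores,
                                 cfg$inclusion_E, cfg$overlap_merge)
      return(call_row("present_genome_only", "six-frame", t2$target,
                      start = gcoord$start, end = gcoord$end,
                      strand = gcoord$strand, score = t2$score,
                      ev = t2$evalue, paralogs = paralogs))
    }
  } else segments <- NULL

  ## Tier 3: relaxed domain-level screen
  for (dom in family$domains %||% list()) {
    d1 <- best_hit(dom$profile, dom$fit, proteome, prot_res,
                   cfg$gap_open, cfg$gap_extend)
    if (is.finite(d1$evalue) && d1$evalue <= cfg$domain_E)
      return(call_row("present", "domain", d1$target, score = d1$score,
                      ev = d1$evalue, paralogs = 1L))
    if (!genome_unchecked && nrow(segments) > 0) {
      seg_seqs <- setNames(segments$aa,
                           sprintf("%s:%+d:%d-%d", segments$contig,
                                   segments$frame, segments$start,
                                   segments$end))
      d2 <- best_hit(dom$profile, dom$fit, seg_seqs, sum(nchar(seg_seqs)),
                     cfg$gap_open, cfg$gap_extend)
      if (is.finite(d2$evalue) && d2$evalue <= cfg$domain_E) {
        i <- which(names(seg_seqs) == d2$target)[1]
        gcoord <- segment_hit_coords(dom$profile, segments[i, ],
                                     cfg$gap_open, cfg$gap_extend)
        return(call_row("present_genome_only", "domain", d2$target,
                        start = gcoord$start, end = gcoord$end,
                        strand = gcoord$strand, score = d2$score,
                        ev = d2$evalue, paralogs = 1L))
      }
    }
  }
  call_row("absent", "none")
}

## Map a profile hit inside a translated segment back to forward-strand
## nucleotide coordinates (1-based inclusive).
segment_hit_coords <- function(profile, seg, gap_open, gap_extend) {
  al <- score_local(profile, seg$aa, gap_open, gap_extend)
  if (length(al$seq_interval) == 0)
    return(list(start = NA_integer_, end = NA_integer_,
                strand = if (seg$frame > 0) "+" else "-"))
  p1 <- al$seq_interval[1]; p2 <- al$seq_interval[2]
  if (seg$frame > 0) {
    start <- seg$start + 3L * (p1 - 1L)
    end <- seg$start + 3L * p2 - 1L
  } else {
    end <- seg$end - 3L * (p1 - 1L)
    start <- seg$end - 3L * p2 + 1L
  }
  list(start = as.integer(start), end = as.integer(end),
       strand = if (seg$frame > 0) "+" else "-")
}

## Non-overlapping qualifying genome hits: greedy by descending bit
## score; intervals overlapping > `frac` of the shorter are merged.
count_paralogs <- function(segments, evalues, scores, threshold, frac) {
  qual <- which(evalues <= threshold)
  if (!length(qual)) return(0L)
  qual <- qual[order(-scores[qual])]
  kept <- list()
  for (i in qual) {
    iv <- list(contig = segments$contig[i],
               s = segments$start[i], e = segments$end[i])
    ok <- TRUE
    for (kv in kept) {
      if (kv$contig != iv$contig) next
      ov <- min(iv$e, kv$e) - max(iv$s, kv$s) + 1
      if (ov > 0 && ov > frac * min(iv$e - iv$s + 1, kv$e - kv$s + 1)) {
        ok <- FALSE; break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- iv
  }
  length(kept)
}

#' Screen every family against every taxon
#'
#' Applies [verify_absence()] to the full (family, taxon) grid,
#' producing one evidence-tiered presence call per cell, with paralog
#' counts (distinct qualifying proteome sequences at tier 1,
#' non-overlapping qualifying genome intervals at tier 2).
#'
#' @param families Named list of family objects (see [verify_absence()]).
#' @param taxa_data Named list: taxon -> `list(proteome =, genome =)`.
#' @param config Threshold configuration; see `default_screen_config()`.
#' @return Data frame of presence calls, one row per (family, taxon).
#' @export
screen_all <- function(families, taxa_data, config = list()) {
  cfg <- utils::modifyList(default_screen_config(), config)
  calls <- list()
  for (tx in names(taxa_data)) {
    td <- taxa_data[[tx]]
    segments <- if (!is.null(td$genome) && length(td$genome) > 0)
      genome_segments(td$genome, cfg$min_seg_len) else NULL
    for (fam in families) {
      calls[[length(calls) + 1L]] <-
        verify_absence(fam, td$proteome %||% character(0), td$genome,
                       cfg, taxon = tx, segments = segments)
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Build a calibrated family object from a seed alignment
#'
#' Convenience constructor: profile + E-value calibration (+ optional
#' domain sub-profiles) ready for [verify_absence()]/[screen_all()].
#'
#' @param seed_msa Seed alignment for the full-length family profile.
#' @param family Family id.
#' @param domain_msas Optional named list of domain sub-alignments.
#' @param alpha,background,n_decoys,seed,gap_open,gap_extend Passed to
#'   [build_profile()] / [calibrate_evalue()].
#' @return List with `family`, `profile`, `fit`, `domains`.
#' @export
calibrate_family <- function(seed_msa, family = "fam",
                             domain_msas = NULL, alpha = 1,
                             background = uniform_background(),
                             n_decoys = 200, seed = 1,
                             gap_open = 3.5, gap_extend = 0.3) {
  profile <- build_profile(seed_msa, alpha, background, family = family)
  fit <- calibrate_evalue(profile, n_decoys = n_decoys, seed = seed,
                          gap_open = gap_open, gap_extend = gap_extend)
  domains <- NULL
  if (!is.null(domain_msas)) {
    domains <- lapply(seq_along(domain_msas), function(i) {
      p <- build_profile(domain_msas[[i]], alpha, background,
                         family = paste0(family, "_dom", i))
      f <- calibrate_evalue(p, n_decoys = n_decoys, seed = seed + 1000 + i,
                            gap_open = gap_open, gap_extend = gap_extend)
      list(profile = p, fit = f)
    })
  }
  list(family = family, profile = profile, fit = fit, domains = domains)
}
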