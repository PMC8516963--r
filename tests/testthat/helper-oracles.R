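# Independent oracles used across the suite. Each is deliberately a
# different route than the implementation: exhaustive enumeration where
# the package uses dynamic programming, labeling enumeration where the
# package uses an MRCA/path construction, a literal codon table where
# the package delegates translation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ---- exhaustive local alignment -------------------------------------
# A local alignment is a set of matched pairs (i_1<...<i_k, j_1<...<j_k)
# of sequence positions and profile columns; internal gaps of length g
# cost gap_open + g*gap_extend on each side independently. Interleavings
# that split a gap run cost strictly more, so enumerating pair sets
# covers every alignment's best realization.
brute_local_score <- function(scores, seq_chars, gap_open, gap_extend) {
  n <- length(seq_chars)
  L <- nrow(scores)
  aa_idx <- match(seq_chars, AA20)
  best <- 0
  for (k in seq_len(min(n, L))) {
    seq_sets <- utils::combn(n, k, simplify = FALSE)
    col_sets <- utils::combn(L, k, simplify = FALSE)
    for (ss in seq_sets) {
      for (cs in col_sets) {
        sc <- 0
        for (t in seq_len(k)) {
          a <- aa_idx[ss[t]]
          sc <- sc + if (is.na(a)) 0 else unname(scores[cs[t], a])
          if (t > 1) {
            gs <- ss[t] - ss[t - 1] - 1   # unmatched sequence residues
            gc_ <- cs[t] - cs[t - 1] - 1  # unmatched profile columns
            if (gs > 0) sc <- sc - (gap_open + gs * gap_extend)
            if (gc_ > 0) sc <- sc - (gap_open + gc_ * gap_extend)
          }
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# ---- Dollo parsimony by labeling enumeration ------------------------
# parent: parent node index per node (0 for root); tips: indices of
# leaves; pattern: logical presence per tip. Enumerates all presence
# labelings of the internal nodes, keeps single-gain Dollo-valid ones,
# and returns the minimum loss count.
brute_dollo_min_losses <- function(parent, tips, pattern) {
  stopifnot(length(tips) == length(pattern))
  if (!any(pattern)) return(0L)
  N <- length(parent)
  internal <- setdiff(seq_len(N), tips)
  state <- logical(N)
  state[tips] <- pattern
  best <- Inf
  n_int <- length(internal)
  for (mask in 0:(2^n_int - 1)) {
    if (n_int > 0)
      state[internal] <- bitwAnd(bitwShiftR(mask, seq_len(n_int) - 1), 1) == 1
    gains <- sum(vapply(seq_len(N), function(v)
      state[v] && (parent[v] == 0 || !state[parent[v]]), TRUE))
    if (gains != 1) next
    losses <- sum(vapply(seq_len(N), function(v)
      !state[v] && parent[v] != 0 && state[parent[v]], TRUE))
    if (losses < best) best <- losses
  }
  as.integer(best)
}

# All rooted binary tree shapes with n leaves (Wedderburn-Etherington),
# as nested pair lists; a leaf is the atom "L".
tree_shapes <- function(n) {
  if (n == 1) return(list("L"))
  out <- list()
  for (a in 1:(n %/% 2)) {
    b <- n - a
    la <- tree_shapes(a); lb <- tree_shapes(b)
    if (a < b) {
      for (x in la) for (y in lb) out[[length(out) + 1]] <- list(x, y)
    } else {  # a == b: unordered pairs with repetition
      for (i in seq_along(la)) for (j in i:length(lb))
        out[[length(out) + 1]] <- list(la[[i]], lb[[j]])
    }
  }
  out
}

# Convert a shape into (newick, parent vector aligned to ape node
# numbering, tip count). ape numbers tips 1..n in newick order and
# internal nodes n+1.. in preorder, so build newick with ordered labels.
shape_to_tree <- function(shape) {
  counter <- 0
  nwk <- function(s) {
    if (identical(s, "L")) {
      counter <<- counter + 1
      return(sprintf("x%d:1", counter))
    }
    sprintf("(%s,%s):1", nwk(s[[1]]), nwk(s[[2]]))
  }
  txt <- paste0(nwk(shape), ";")
  tr <- ape::read.tree(text = txt)
  n <- length(tr$tip.label)
  parent <- integer(n + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  list(tree = tr, parent = parent, ntip = n)
}

# ---- literal standard genetic code ----------------------------------
# Codon order TTT, TTC, TTA, TTG, TCT, ... (bases ordered T, C, A, G).
STD_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

oracle_translate_codon <- function(codon) {
  if (grepl("N", codon)) return("X")
  unname(STD_CODE[codon])
}

oracle_revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]),
        collapse = "")
}

# Straightforward re-implementation of six-frame segment extraction.
oracle_six_frame <- function(dna, min_len) {
  L <- nchar(dna)
  segs <- list()
  for (sgn in c(1, -1)) {
    s <- if (sgn > 0) dna else oracle_revcomp(dna)
    for (off in 0:2) {
      ncod <- (L - off) %/% 3
      if (ncod < 1) next
      aa <- character(ncod); brk <- logical(ncod)
      for (i in seq_len(ncod)) {
        codon <- substr(s, off + 3 * (i - 1) + 1, off + 3 * i)
        aa[i] <- oracle_translate_codon(codon)
        brk[i] <- aa[i] == "*" || codon == "NNN"
      }
      i <- 1
      while (i <= ncod) {
        if (brk[i]) { i <- i + 1; next }
        j <- i
        while (j < ncod && !brk[j + 1]) j <- j + 1
        if (j - i + 1 >= min_len) {
          s1 <- off + 3 * (i - 1) + 1; s2 <- off + 3 * j
          segs[[length(segs) + 1]] <- data.frame(
            frame = sgn * (off + 1),
            start = if (sgn > 0) s1 else L - s2 + 1,
            end = if (sgn > 0) s2 else L - s1 + 1,
            aa = paste(aa[i:j], collapse = ""),
            stringsAsFactors = FALSE)
        }
        i <- j + 1
      }
    }
  }
  if (!length(segs))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa = character(0)))
  out <- do.call(rbind, segs)
  out[order(out$frame, out$start), ]
}

# ---- misc -----------------------------------------------------------
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}
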