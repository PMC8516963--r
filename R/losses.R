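## Presence/absence matrix assembly, Dollo parsimony loss mapping,
## complex summaries and BUSCO-style completeness arithmetic.

PRESENCE_STATES <- c("present", "present_genome_only", "absent")

#' Assemble a presence/absence matrix from screening calls
#'
#' @param calls Data frame of presence calls (from [screen_all()] or
#'   read from a calls TSV) covering a complete (family, taxon) grid.
#' @return Object of class `presence_matrix`: `families`, `taxa`,
#'   `state` (family x taxon character matrix), `paralogs` (integer
#'   matrix or `NULL`). `present_genome_only` counts as present for
#'   downstream reconstruction but the annotation is retained.
#' @export
build_matrix <- function(calls) {
  stopifnot(all(c("family", "taxon", "state") %in% names(calls)))
  if (anyDuplicated(calls[, c("family", "taxon")]))
    stop("invalid-input: duplicate (family, taxon) call", call. = FALSE)
  if (!all(calls$state %in% PRESENCE_STATES))
    stop("invalid-input: unknown state", call. = FALSE)
  families <- unique(calls$family)
  taxa <- unique(calls$taxon)
  if (nrow(calls) != length(families) * length(taxa))
    stop("invalid-input: calls do not cover the full grid", call. = FALSE)
  state <- matrix(NA_character_, length(families), length(taxa),
                  dimnames = list(families, taxa))
  state[cbind(calls$family, calls$taxon)] <- calls$state
  if (anyNA(state))
    stop("invalid-input: calls do not cover the full grid", call. = FALSE)
  paralogs <- NULL
  if ("paralogs" %in% names(calls)) {
    paralogs <- matrix(0L, length(families), length(taxa),
                       dimnames = list(families, taxa))
    paralogs[cbind(calls$family, calls$taxon)] <- as.integer(calls$paralogs)
  }
  structure(list(families = families, taxa = taxa, state = state,
                 paralogs = paralogs),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d families x %d taxa\n",
              length(x$families), length(x$taxa)))
  invisible(x)
}

## logical presence (present_genome_only treated as present)
presence_logical <- function(pm) {
  pm$state != "absent"
}

#' Dollo parsimony reconstruction for one family
#'
#' Under Dollo parsimony (a single gain, any number of irreversible
#' losses) the minimum-loss labeling places the origin at the most
#' recent common ancestor of all present tips; the loss events are the
#' branches leading to the maximal subtrees below the origin that
#' contain no present tip.
#'
#' @param tree Rooted `phylo` tree.
#' @param column Named logical vector (tip label -> present) or a
#'   character vector of presence states.
#' @return List with `origin` (node number; a tip number when only one
#'   tip is present), `losses` (data frame `branch_child`, `type`),
#'   `n_losses`, and `no_origin` (`TRUE` for an all-absent column, in
#'   which case origin is `NA` and there are no events).
#' @export
dollo_reconstruct <- function(tree, column) {
  ntip <- length(tree$tip.label)
  if (is.character(column)) column <- column != "absent"
  if (is.null(names(column)) && length(column) == ntip)
    names(column) <- tree$tip.label
  present_tips <- which(tree$tip.label %in% names(column)[column])
  if (length(present_tips) == 0)
    return(list(origin = NA_integer_,
                losses = data.frame(branch_child = integer(0),
                                    type = character(0),
                                    stringsAsFactors = FALSE),
                n_losses = 0L, no_origin = TRUE))
  origin <- if (length(present_tips) == 1) present_tips else
    ape::getMRCA(tree, present_tips)

  ## kept set: nodes on paths from origin to present tips
  kept <- rep(FALSE, max(tree$edge))
  kept[origin] <- TRUE
  for (tp in present_tips) {
    nd <- tp
    while (nd != origin && !kept[nd]) {
      kept[nd] <- TRUE
      nd <- tree$edge[tree$edge[, 2] == nd, 1]
    }
  }
  ## loss edges: kept parent -> unkept child, within origin's subtree
  in_sub <- rep(FALSE, max(tree$edge))
  in_sub[c(origin, node_descendants(tree, origin))] <- TRUE
  loss_children <- tree$edge[kept[tree$edge[, 1]] &
                             !kept[tree$edge[, 2]] &
                             in_sub[tree$edge[, 1]], 2]
  list(origin = as.integer(origin),
       losses = data.frame(branch_child = as.integer(loss_children),
                           type = rep("loss", length(loss_children)),
                           stringsAsFactors = FALSE),
       n_losses = length(loss_children), no_origin = FALSE)
}

#' Dollo reconstruction for every family of a presence matrix
#'
#' @param tree Rooted `phylo` tree whose tip labels match the matrix
#'   taxa.
#' @param pm A `presence_matrix`.
#' @param exclude Character vector of family ids to skip (e.g. families
#'   with suspected multiple independent gains).
#' @return Data frame of events: `family`, `node` (child node of the
#'   branch), `type` (`gain` at the origin node, `loss` below it).
#' @export
reconstruct_all <- function(tree, pm, exclude = character(0)) {
  stopifnot(inherits(pm, "presence_matrix"))
  pres <- presence_logical(pm)
  ev <- list()
  for (fam in setdiff(pm$families, exclude)) {
    rec <- dollo_reconstruct(tree, pres[fam, ])
    if (rec$no_origin) next
    ev[[length(ev) + 1L]] <- data.frame(
      family = fam,
      node = c(rec$origin, rec$losses$branch_child),
      type = c("gain", rec$losses$type), stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(family = character(0), node = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Complex status per taxon
#'
#' A complex is `full` in a taxon when all member families are present
#' (genome-only detections count as present), `absent` when none are,
#' and `partial` otherwise.
#'
#' @param pm A `presence_matrix`.
#' @param complexes Data frame with columns `complex` and `family`
#'   (one row per member), or a named list complex -> family ids.
#' @return Data frame: `taxon`, `complex`, `n_members`, `n_present`,
#'   `status`.
#' @export
complex_status <- function(pm, complexes) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.list(complexes) && !is.data.frame(complexes))
    complexes <- data.frame(
      complex = rep(names(complexes), lengths(complexes)),
      family = unlist(complexes, use.names = FALSE),
      stringsAsFactors = FALSE)
  unknown <- setdiff(complexes$family, pm$families)
  if (length(unknown))
    stop("unknown complex member families: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pres <- presence_logical(pm)
  out <- list()
  for (cx in unique(complexes$complex)) {
    members <- complexes$family[complexes$complex == cx]
    for (tx in pm$taxa) {
      np <- sum(pres[members, tx])
      status <- if (np == length(members)) "full"
      else if (np == 0) "absent" else "partial"
      out[[length(out) + 1L]] <- data.frame(
        taxon = tx, complex = cx, n_members = length(members),
        n_present = np, status = status, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' BUSCO-style completeness percentage
#'
#' Integer percentage of a reference single-copy ortholog set recovered
#' in a proteome, rounded to the nearest integer with halves away from
#' zero (217 of 245 gives 89, 207 of 245 gives 84).
#'
#' @param n_found Number of reference orthologs recovered (0..n_max).
#' @param n_max Size of the reference set (> 0).
#' @return Integer percentage.
#' @export
busco_percentage <- function(n_found, n_max) {
  if (any(n_max <= 0)) stop("invalid-argument: n_max must be > 0",
                            call. = FALSE)
  if (any(n_found < 0) || any(n_found > n_max))
    stop("invalid-argument: n_found must be in [0, n_max]", call. = FALSE)
  x <- 100 * n_found / n_max
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Per-branch loss counts by complex
#'
#' Tabulates Dollo loss events per tree branch (identified by its child
#' node) and per complex; families outside any complex are grouped
#' under `"(none)"`. Totals are conserved: the table sums to the number
#' of loss events.
#'
#' @param tree Rooted `phylo` tree.
#' @param events Event table from [reconstruct_all()].
#' @param complexes Optional complex definition (as in
#'   [complex_status()]).
#' @return Branch x complex integer matrix of loss counts; rownames are
#'   child-node numbers.
#' @export
branch_loss_summary <- function(tree, events, complexes = NULL) {
  losses <- events[events$type == "loss", , drop = FALSE]
  fam2cx <- NULL
  if (!is.null(complexes)) {
    if (is.list(complexes) && !is.data.frame(complexes))
      complexes <- data.frame(
        complex = rep(names(complexes), lengths(complexes)),
        family = unlist(complexes, use.names = FALSE),
        stringsAsFactors = FALSE)
    fam2cx <- setNames(complexes$complex, complexes$family)
  }
  cx <- if (is.null(fam2cx)) rep("(none)", nrow(losses)) else {
    v <- unname(fam2cx[losses$family]); v[is.na(v)] <- "(none)"; v
  }
  branches <- sort(unique(tree$edge[, 2]))
  cx_levels <- sort(unique(c(cx, if (!is.null(fam2cx)) unique(fam2cx))))
  if (!length(cx_levels)) cx_levels <- "(none)"
  tab <- matrix(0L, length(branches), length(cx_levels),
                dimnames = list(as.character(branches), cx_levels))
  if (nrow(losses) > 0) {
    for (i in seq_len(nrow(losses))) {
      tab[as.character(losses$node[i]), cx[i]] <-
        tab[as.character(losses$node[i]), cx[i]] + 1L
    }
  }
  tab
}
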