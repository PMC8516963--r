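calls_grid <- function(df) df  # plain calls; build_matrix needs no tier

test_that("build_matrix assembles and validates the grid", {
  one <- calls_grid(data.frame(family = "f1", taxon = "t1",
                               state = "present", paralogs = 1))
  pm <- build_matrix(one)
  expect_equal(dim(pm$state), c(1, 1))
  expect_equal(pm$state["f1", "t1"], "present")

  dup <- rbind(one, one)
  expect_error(build_matrix(dup), "duplicate")

  partial <- calls_grid(data.frame(
    family = c("f1", "f1", "f2"), taxon = c("t1", "t2", "t1"),
    state = "present"))
  expect_error(build_matrix(partial), "grid")

  bad <- one; bad$state <- "maybe"
  expect_error(build_matrix(bad), "state")
})

test_that("Dollo reconstruction matches hand-worked cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

  all_present <- dollo_reconstruct(tr, c(A = TRUE, B = TRUE, C = TRUE,
                                         D = TRUE))
  expect_equal(all_present$origin, 5L)  # root
  expect_equal(all_present$n_losses, 0L)

  single <- dollo_reconstruct(tr, c(A = FALSE, B = FALSE, C = TRUE,
                                    D = FALSE))
  expect_equal(single$origin, which(tr$tip.label == "C"))
  expect_equal(single$n_losses, 0L)

  crossed <- dollo_reconstruct(tr, c(A = TRUE, B = FALSE, C = TRUE,
                                     D = FALSE))
  expect_equal(crossed$origin, 5L)
  expect_setequal(crossed$losses$branch_child,
                  which(tr$tip.label %in% c("B", "D")))

  empty <- dollo_reconstruct(tr, c(A = FALSE, B = FALSE, C = FALSE,
                                   D = FALSE))
  expect_true(empty$no_origin)
  expect_equal(empty$n_losses, 0L)
})

test_that("reconstruction attains the brute-force minimum on random trees", {
  for (s in 1:25) {
    n <- sample(3:7, 1)
    tr <- simulate_tree(n, seed = 700 + s)
    parent <- integer(n + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    pattern <- runif(n) < 0.5
    if (!any(pattern)) pattern[sample(n, 1)] <- TRUE
    rec <- dollo_reconstruct(tr, setNames(pattern, tr$tip.label))
    bf <- brute_dollo_min_losses(parent, seq_len(n), pattern)
    expect_equal(rec$n_losses, bf)
  }
})

test_that("complex status partitions into full, partial, absent", {
  calls <- calls_grid(expand.grid(family = c("f1", "f2", "f3", "f4"),
                                  taxon = c("t1", "t2", "t3"),
                                  stringsAsFactors = FALSE))
  calls$state <- "present"
  calls$state[calls$taxon == "t2" & calls$family %in% c("f1", "f2")] <-
    "absent"
  calls$state[calls$taxon == "t3"] <- "absent"
  pm <- build_matrix(calls)
  st <- complex_status(pm, list(CX = c("f1", "f2", "f3", "f4")))
  expect_equal(st$status[st$taxon == "t1"], "full")
  expect_equal(st$status[st$taxon == "t2"], "partial")
  expect_equal(st$status[st$taxon == "t3"], "absent")
  # one status per cell
  expect_equal(nrow(st), 3)
  expect_error(complex_status(pm, list(CX = c("f1", "nope"))), "unknown")
})

test_that("genome-only detections count as present downstream", {
  calls <- calls_grid(data.frame(
    family = c("f1", "f2"), taxon = "t1",
    state = c("present_genome_only", "absent")))
  pm <- build_matrix(calls)
  st <- complex_status(pm, list(CX = c("f1")))
  expect_equal(st$status, "full")
})

test_that("BUSCO-style percentages reproduce the reference arithmetic", {
  expect_identical(busco_percentage(217, 245), 89L)
  expect_identical(busco_percentage(245, 245), 100L)
  expect_identical(busco_percentage(0, 245), 0L)
  # half away from zero
  expect_identical(busco_percentage(1, 200), 1L)    # 0.5 -> 1
  expect_identical(busco_percentage(3, 200), 2L)    # 1.5 -> 2
  expect_error(busco_percentage(1, 0), "invalid-argument")
  expect_error(busco_percentage(-1, 10), "invalid-argument")
  expect_error(busco_percentage(11, 10), "invalid-argument")
})

test_that("branch loss summaries conserve totals", {
  tr <- simulate_tree(6, seed = 12)
  calls <- calls_grid(expand.grid(family = paste0("f", 1:4),
                                  taxon = tr$tip.label,
                                  stringsAsFactors = FALSE))
  calls$state <- "present"
  # one family absent in a single tip: exactly one loss on that branch
  calls$state[calls$family == "f2" & calls$taxon == "t3"] <- "absent"
  pm <- build_matrix(calls)
  ev <- reconstruct_all(tr, pm)
  tab <- branch_loss_summary(tr, ev,
                             complexes = list(CX = c("f1", "f2"),
                                              CY = c("f3", "f4")))
  expect_equal(sum(tab), sum(ev$type == "loss"))
  expect_equal(sum(tab), 1)
  expect_equal(unname(tab[as.character(which(tr$tip.label == "t3")),
                          "CX"]), 1L)

  # no losses anywhere: all-zero table
  calls$state <- "present"
  ev0 <- reconstruct_all(tr, build_matrix(calls))
  tab0 <- branch_loss_summary(tr, ev0)
  expect_true(all(tab0 == 0))
})

test_that("simulated losses with a perfect screen are recovered", {
  for (s in 1:10) {
    tr <- simulate_tree(8, seed = 800 + s)
    ft <- evolve_family(tr, root_len = 20, sub_rate = 0, loss_rate = 0.3,
                        seed = 900 + s, family = "fam")
    present <- !vapply(ft$tip_seqs, is.na, TRUE)
    if (!any(present)) next
    rec <- dollo_reconstruct(tr, present)
    # parsimony can only need as many losses as truly happened below
    # the inferred origin
    expect_lte(rec$n_losses, length(ft$loss_branches))
    # when every true lost clade is maximal (its parent retains a
    # surviving lineage) and lies below the origin, the minimal
    # labeling recovers the true loss set exactly
    origin_desc <- c(rec$origin,
                     orthotrace:::node_descendants(tr, rec$origin))
    ntip <- length(tr$tip.label)
    maximal <- vapply(ft$loss_branches, function(lb) {
      par <- tr$edge[tr$edge[, 2] == lb, 1]
      sibs <- setdiff(tr$edge[tr$edge[, 1] == par, 2], lb)
      any(vapply(sibs, function(sb) {
        below <- c(sb, orthotrace:::node_descendants(tr, sb))
        any(present[tr$tip.label[below[below <= ntip]]])
      }, TRUE))
    }, TRUE)
    if (all(ft$loss_branches %in% origin_desc) && all(maximal))
      expect_setequal(rec$losses$branch_child, ft$loss_branches)
  }
})
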