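panel <- default_marker_panel()

test_that("the default epsilon ladder is the documented 12-value sweep", {
  expect_equal(contrabin:::DEFAULT_EPS_LADDER,
               c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45,
                 0.5, 0.55))
  expect_equal(contrabin:::DEFAULT_CONT_LADDER, c(0.1, 0.2, 0.3, 0.4, 0.5, 1))
})

test_that("well-separated clouds never mix in any sweep run", {
  set.seed(23)
  # two tight clouds on the unit sphere, far apart after normalization
  A <- matrix(rnorm(20 * 8, 0, 0.002), 20, 8)
  A[, 1] <- A[, 1] + 1
  B <- matrix(rnorm(20 * 8, 0, 0.002), 20, 8)
  B[, 2] <- B[, 2] + 1
  X <- rbind(A, B)
  rownames(X) <- c(paste0("a", 1:20), paste0("b", 1:20))
  sw <- dbscan_sweep(X, min_samples = 5)
  for (run in sw$runs) {
    labs <- run$labels[run$labels > 0]
    if (length(labs) == 0) next
    for (cl in unique(labs)) {
      members <- names(labs)[labs == cl]
      expect_true(all(startsWith(members, "a")) ||
                    all(startsWith(members, "b")))
    }
    # against the eps-neighbourhood-graph oracle on core points
    comp <- brute_core_components(X, run$eps, 5)
    core <- !is.na(comp)
    if (any(core)) {
      got <- run$labels[core]
      expect_true(all(got > 0))
      # same partition up to label permutation
      expect_equal(length(unique(comp[core])), length(unique(got)))
      expect_true(all(tapply(got, comp[core],
                             function(v) length(unique(v))) == 1))
    }
  }
})

test_that("identical points form one cluster at every epsilon", {
  X <- matrix(1, 12, 4, dimnames = list(paste0("c", 1:12), NULL))
  sw <- dbscan_sweep(X, min_samples = 5)
  for (run in sw$runs) {
    expect_equal(unname(run$labels), rep(1L, 12))
  }
})

test_that("the eps-neighbourhood graph is monotone in eps", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Xn <- X / sqrt(rowSums(X^2))
  D <- as.matrix(dist(Xn))
  eps <- contrabin:::DEFAULT_EPS_LADDER
  for (i in seq_len(length(eps) - 1)) {
    expect_true(all((D <= eps[i]) <= (D <= eps[i + 1])))
  }
})

test_that("a full-panel bin is selected at the strictest level", {
  ann <- marker_annotation(list(c1 = panel[1:60], c2 = panel[61:107]), panel)
  lens <- c(c1 = 5e5, c2 = 4e5, junk = 1e5)
  sel <- ensemble_select(list(c("c1", "c2"), "junk"), ann, lens)
  expect_length(sel, 1L)
  expect_setequal(sel[[1]]$contigs, c("c1", "c2"))
  expect_equal(sel[[1]]$cont_level, 0.1)
  expect_equal(sel[[1]]$score$f1, 1)
})

test_that("zero-marker candidates are never selected", {
  ann <- marker_annotation(list(c1 = panel[1:20]), panel)
  lens <- c(c1 = 1e5, x = 1e6, y = 1e6)
  sel <- ensemble_select(list("x", "y", "c1"), ann, lens)
  expect_length(sel, 1L)
  expect_equal(sel[[1]]$contigs, "c1")
})

test_that("greedy integration matches the exhaustive oracle on random instances", {
  set.seed(71)
  for (inst in 1:100) {
    pool <- paste0("c", 1:12)
    lens <- setNames(sample(1e4:1e6, 12), pool)
    hits <- random_annotation(pool, panel, mean_hits = 8)
    ann <- marker_annotation(hits, panel)
    n_runs <- sample(1:4, 1)
    cands <- list()
    for (r in seq_len(n_runs)) {
      for (b in seq_len(sample(1:6, 1))) {
        cands[[length(cands) + 1L]] <- sample(pool, sample(1:6, 1))
      }
    }
    got <- ensemble_select(cands, ann, lens)
    got_bins <- lapply(got, function(s) sort(s$contigs))
    want_bins <- brute_ensemble(cands, hits, lens)
    expect_equal(got_bins, want_bins, info = paste("instance", inst))
    # selected bins are pairwise disjoint
    all_ids <- unlist(got_bins)
    expect_false(anyDuplicated(all_ids) > 0)
    # contamination at selection time below the ladder level
    for (s in got) expect_lt(s$score$contamination, s$cont_level)
  }
})

test_that("selection order follows f1 when candidates do not interact", {
  # with pairwise-disjoint candidates, removals never rescore a survivor, so
  # bins within one ladder level must come out in non-increasing f1 order
  # (with overlap, rescoring after a removal can legitimately raise a later
  # candidate's f1, e.g. by stripping its duplicated markers)
  set.seed(19)
  pool <- paste0("c", 1:30)
  lens <- setNames(rep(1e5, 30), pool)
  hits <- random_annotation(pool, panel, mean_hits = 10)
  ann <- marker_annotation(hits, panel)
  cands <- split(pool, rep(1:6, each = 5))
  sel <- ensemble_select(unname(cands), ann, lens)
  by_level <- split(vapply(sel, function(s) s$score$f1, 0),
                    vapply(sel, function(s) s$cont_level, 0))
  for (f1s in by_level) expect_false(is.unsorted(rev(f1s)))
})

test_that("leftover handling reports or promotes unselected contigs", {
  sel <- list(list(contigs = c("a", "b"), score = NULL, cont_level = 0.1))
  lens <- c(a = 3e5, b = 2e5, big = 3e5, small = 1e4)
  off <- handle_noise(sel, names(lens), lens, emit_leftover = FALSE)
  expect_setequal(off$unbinned, c("big", "small"))
  expect_length(off$bins, 1L)
  on <- handle_noise(sel, names(lens), lens, emit_leftover = TRUE)
  expect_length(on$bins, 2L)
  expect_equal(on$bins[[2]], "big")
  expect_equal(on$unbinned, "small")
  # all leftovers below threshold: no extra bins
  none <- handle_noise(sel, names(lens), lens, emit_leftover = TRUE,
                       min_bin_size = 1e9)
  expect_length(none$bins, 1L)
})
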