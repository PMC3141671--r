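test_that("event models are validated against the backbone", {
  bb <- kcna_backbone()$arrangements[[1]]
  ev <- kcna_events()
  expect_silent(dupetime:::validate_events(ev, bb))
  # unmapped node
  bad <- event_model(c("P12", "P36"), c("e", "e"), "e")
  expect_error(dupetime:::validate_events(bad, bb), "not mapped")
  # ancestrally related nodes cannot share an event
  bad2 <- event_model(
    c("P12", "P36", "P510", "C1", "C2", "A4", "RN"),
    c("x", "e", "e", "x", "e2", "e3", "e4"), "e")   # C1 ancestral to P12
  expect_error(dupetime:::validate_events(bad2, bb), "ancestrally related")
})

test_that("single placements classify by the ancestor/descendant/uncle rule", {
  bb <- kcna_backbone()
  pl <- enumerate_placements(bb, "q")
  tm <- classify_placements(pl)
  first <- tm[tm$arrangement_id == "pairing_36_510", ]
  row_for <- function(b) first[first$branch_id == b, ]

  # root-branch graft: every backbone duplication postdates the split
  r <- row_for("ROOT")
  expect_identical(c(r$n_bef, r$n_aft, r$n_und), c(0, 7, 0))
  expect_identical(r$scenario, "I")

  # graft inside a paralog pair: everything predates the split, including
  # the tandem node ancestral only to the other pairs
  r <- row_for("KCNA1")
  expect_identical(c(r$n_bef, r$n_aft, r$n_und), c(7, 0, 0))
  expect_identical(r$scenario, "II")

  # graft on the KCNA4 terminal: only root and KCNA4-stem events are
  # ordered; the cluster stays undetermined
  r <- row_for("KCNA4")
  expect_identical(c(r$n_bef, r$n_aft, r$n_und), c(2, 0, 5))
  expect_identical(r$scenario, "ambiguous")

  # graft just above a paralog pair: the pair node makes the cluster
  # duplication "after", pulling all three of its nodes with it
  r <- row_for("P12")
  expect_identical(c(r$n_bef, r$n_aft, r$n_und), c(3, 3, 1))
  expect_identical(r$scenario, "I")
})

test_that("the 45 placements split 21 / 18 / 6 across scenarios", {
  bb <- kcna_backbone()
  tm <- classify_placements(enumerate_placements(bb, "q"))
  expect_identical(scenario_counts(tm),
                   c(I = 21L, II = 18L, ambiguous = 6L))
  # per-arrangement symmetry
  one <- backbone_spec(bb$arrangements[[1]], events = kcna_events())
  tm1 <- classify_placements(enumerate_placements(one, "q"))
  expect_identical(scenario_counts(tm1),
                   c(I = 7L, II = 6L, ambiguous = 2L))
})

test_that("a minimal 3-leaf backbone classifies by hand-checked counts", {
  tr <- read_newick(text = "((A:0.1,B:0.1)ab:0.1,C:0.1)r;")
  ev <- event_model(c("ab", "r"), c("e_ab", "e_r"), focal = "e_ab")
  tm <- classify_placements(
    enumerate_placements(backbone_spec(tr, events = ev), "Q"), ev)
  expect_identical(scenario_counts(tm),
                   c(I = 2L, II = 2L, ambiguous = 1L))
  expect_setequal(tm$branch_id[tm$scenario == "II"], c("A", "B"))
  expect_setequal(tm$branch_id[tm$scenario == "I"], c("ab", "ROOT"))
  expect_identical(tm$branch_id[tm$scenario == "ambiguous"], "C")
})

test_that("node counts always partition the backbone internal nodes", {
  bb <- kcna_backbone()
  tm <- classify_placements(enumerate_placements(bb, "q"))
  expect_true(all(tm$n_bef + tm$n_aft + tm$n_und == 7))
})

test_that("weighted summaries conserve probability and node counts", {
  bb <- kcna_backbone()
  tm <- classify_placements(enumerate_placements(bb, "q"))

  # degenerate weight on the KCNA1 placement of arrangement 1
  w <- as.numeric(tm$branch_id == "KCNA1" &
                  tm$arrangement_id == "pairing_36_510")
  s <- summarize_scenarios(w, tm)
  expect_equal(unlist(s), c(P_I = 0, P_II = 1, N_bef = 7, N_aft = 0))

  # uniform weights: brute-force averages over the full enumeration
  s_u <- summarize_scenarios(rep(1 / 45, 45), tm)
  expect_equal(s_u$P_I, 24 / 45, tolerance = 1e-12)
  expect_equal(s_u$P_II, 21 / 45, tolerance = 1e-12)
  expect_equal(s_u$N_bef, 68 / 15, tolerance = 1e-12)
  expect_equal(s_u$N_aft, 37 / 15, tolerance = 1e-12)

  # conservation for arbitrary random weight vectors
  set.seed(4)
  for (i in 1:25) {
    w <- rexp(45)
    w <- w / sum(w)
    s <- summarize_scenarios(w, tm)
    expect_equal(s$P_I + s$P_II, 1, tolerance = 1e-12)
    expect_equal(s$N_bef + s$N_aft, 7, tolerance = 1e-12)
  }
})

test_that("moving weight from scenario I to II raises P_II and N_bef", {
  bb <- kcna_backbone()
  tm <- classify_placements(enumerate_placements(bb, "q"))
  i_idx <- which(tm$scenario == "I")[1]
  ii_idx <- which(tm$scenario == "II")[1]
  w <- rep(1 / 45, 45)
  s0 <- summarize_scenarios(w, tm)
  w2 <- w
  w2[ii_idx] <- w2[ii_idx] + w2[i_idx]
  w2[i_idx] <- 0
  s1 <- summarize_scenarios(w2, tm)
  expect_gt(s1$P_II, s0$P_II)
  expect_gte(s1$N_bef, s0$N_bef)
})

test_that("event maps round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(kcna_events(), f)
  ev <- read_events(f)
  expect_identical(ev$nodes, kcna_events()$nodes)
  expect_identical(ev$focal, "cluster_dup")
})
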