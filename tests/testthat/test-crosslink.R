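# Cross-link insertion: enzymatic (telopeptide-anchored) and AGE
# (helical-region) bonds.

test_that("full enzymatic content gives two cross-linked ends per molecule", {
  fib <- cached_mini_minimized()
  # capture widened to 70 A so the axially-aligned leftmost pair can link;
  # the single rightmost-protruding chain end has no foreign helical bead
  # within hundreds of A (finite-bundle boundary) and must fall short
  cfg <- crosslink_config(ecl_content = 100, ecl_valence = "divalent",
                          capture_radius = 70, seed = 5)
  out <- insert_ecl(fib, cfg)
  b <- out$topology$bonds
  ecl <- b[b$species == "ecl_divalent", ]
  expect_equal(nrow(ecl) + attr(out, "ecl_shortfall"), 2 * out$n_molecules)
  expect_equal(attr(out, "ecl_shortfall"), 1L)
  # anchors are terminal telopeptide beads; one cross-link per end
  ends <- fibrilmd:::telopeptide_ends(out$system)
  expect_true(all(ecl$i %in% ends$bead))
  expect_false(any(duplicated(ecl$i)))
  # every molecule whose two ends have partners carries exactly two
  anchors_per_mol <- table(factor(out$system$molecule[ecl$i],
                                  levels = 1:out$n_molecules))
  expect_equal(sum(anchors_per_mol == 2), out$n_molecules - 1L)
  expect_equal(sum(anchors_per_mol), 2 * out$n_molecules - 1L)
  # partners are helical beads of a different molecule within range
  expect_true(all(out$system$role[ecl$j] == "helical"))
  expect_true(all(out$system$molecule[ecl$i] != out$system$molecule[ecl$j]))
  r <- sqrt(rowSums((out$system$pos[ecl$j, ] - out$system$pos[ecl$i, ])^2))
  expect_true(all(r <= cfg$capture_radius))
  # census agrees with the nominal two-per-molecule density up to the
  # single orphaned end
  cs <- crosslink_census(out)
  expect_equal(cs$density[cs$species == "ecl_divalent"],
               (2 * out$n_molecules - 1) / out$n_molecules)
  # at the default capture radius the interior ends still all link; only
  # outward-facing terminal ends can fall short in a finite bundle
  out28 <- insert_ecl(fib, crosslink_config(ecl_content = 100,
                                            ecl_valence = "divalent", seed = 5))
  n28 <- sum(out28$topology$bonds$species == "ecl_divalent")
  expect_equal(n28 + attr(out28, "ecl_shortfall"), 2 * fib$n_molecules)
  expect_lte(attr(out28, "ecl_shortfall"), 3L)
})

test_that("trivalent cross-links join three molecules through one anchor", {
  fib <- cached_mini_minimized()
  cfg <- crosslink_config(ecl_content = 50, ecl_valence = "trivalent", seed = 5)
  out <- insert_ecl(fib, cfg)
  b <- out$topology$bonds
  tri <- b[b$species == "ecl_trivalent", ]
  anchors <- unique(tri$i)
  expect_equal(length(anchors), round(0.5 * 2 * out$n_molecules) -
                 attr(out, "ecl_shortfall"))
  for (a in anchors) {
    partners <- tri$j[tri$i == a]
    mols <- out$system$molecule[partners]
    expect_equal(length(partners), 2L)
    expect_equal(length(unique(mols)), 2L)       # two distinct molecules
    expect_false(out$system$molecule[a] %in% mols)
  }
})

test_that("zero content and zero density leave the topology unchanged", {
  fib <- cached_mini()
  cfg <- crosslink_config(ecl_content = 0, n_age = 0)
  expect_identical(insert_ecl(fib, cfg)$topology$bonds, fib$topology$bonds)
  expect_identical(insert_ages(fib, cfg)$topology$bonds, fib$topology$bonds)
})

test_that("half content selects distinct ends, none doubled", {
  fib <- cached_mini_minimized()
  cfg <- crosslink_config(ecl_content = 50, ecl_valence = "divalent", seed = 9)
  out <- insert_ecl(fib, cfg)
  ecl <- out$topology$bonds[out$topology$bonds$species == "ecl_divalent", ]
  n_ends <- 2 * out$n_molecules
  expect_equal(nrow(ecl) + attr(out, "ecl_shortfall"), round(0.5 * n_ends))
  expect_false(any(duplicated(ecl$i)))
})

test_that("AGE insertion meets its count contract and site exclusions", {
  fib <- cached_mini_minimized()
  for (na in c(0.5, 2, 10)) {
    cfg <- crosslink_config(n_age = na, seed = 17)
    out <- insert_ages(fib, cfg)
    ages <- out$topology$bonds[out$topology$bonds$species == "age", ]
    expect_equal(nrow(ages), round(na * out$n_molecules))
    # both endpoints helical, never telopeptide/extension/clamp
    expect_true(all(out$system$role[ages$i] == "helical"))
    expect_true(all(out$system$role[ages$j] == "helical"))
    expect_true(all(out$system$molecule[ages$i] != out$system$molecule[ages$j]))
    r <- sqrt(rowSums((out$system$pos[ages$j, ] - out$system$pos[ages$i, ])^2))
    expect_true(all(r <= cfg$capture_radius))
    # no duplicate bond between the same bead pair
    keys <- paste(pmin(ages$i, ages$j), pmax(ages$i, ages$j))
    expect_false(any(duplicated(keys)))
    cs <- crosslink_census(out)
    expect_equal(cs$density[cs$species == "age"],
                 round(na * out$n_molecules) / out$n_molecules)
  }
  # sub-unity density: hosts drawn molecule-first
  cfg <- crosslink_config(n_age = 0.5, seed = 3)
  out <- insert_ages(fib, cfg)
  ages <- out$topology$bonds[out$topology$bonds$species == "age", ]
  expect_equal(nrow(ages), round(0.5 * fib$n_molecules))
})

test_that("infeasible AGE requests are rejected with the feasible maximum", {
  fib <- cached_mini_minimized()
  expect_error(insert_ages(fib, crosslink_config(n_age = 1e5)),
               "only [0-9]+ distinct eligible site pairs")
})

test_that("insertion is deterministic under a fixed seed", {
  fib <- cached_mini_minimized()
  cfg <- crosslink_config(ecl_content = 75, ecl_valence = "divalent",
                          n_age = 3, seed = 23)
  a <- insert_ages(insert_ecl(fib, cfg), cfg)
  b <- insert_ages(insert_ecl(fib, cfg), cfg)
  expect_identical(a$topology$bonds, b$topology$bonds)
})

test_that("census counts are invariant under rigid translation", {
  fib <- cached_mini_minimized()
  out <- insert_ages(fib, crosslink_config(n_age = 5, seed = 2))
  cs1 <- crosslink_census(out)
  out$system$pos <- out$system$pos + rep(c(100, -50, 3), each = nrow(out$system$pos))
  expect_identical(crosslink_census(out), cs1)
})

test_that("AGE attachment frequencies follow uniform site-pair selection", {
  fib <- cached_mini_minimized()
  sys <- fib$system
  eligible <- which(sys$role == "helical")
  pr <- fibrilmd:::cg_close_pairs(sys$pos[eligible, , drop = FALSE], 28)
  mi <- sys$molecule[eligible[pr[, 1] + 1L]]
  mj <- sys$molecule[eligible[pr[, 2] + 1L]]
  keep <- mi != mj
  # expected attachment share of each molecule under uniform pair draws
  share <- table(factor(c(mi[keep], mj[keep]), levels = 1:fib$n_molecules))
  share <- share / sum(share)
  counts <- integer(fib$n_molecules)
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    out <- insert_ages(fib, crosslink_config(n_age = 1, seed = 1000 + s))
    ages <- out$topology$bonds[out$topology$bonds$species == "age", ]
    tab <- table(factor(c(sys$molecule[ages$i], sys$molecule[ages$j]),
                        levels = 1:fib$n_molecules))
    counts <- counts + as.integer(tab)
  }
  chi <- stats::chisq.test(counts, p = as.numeric(share))
  expect_gt(chi$p.value, 0.01)
})

test_that("pipeline ordering is enforced in strict mode", {
  fib <- cached_mini()   # never equilibrated
  cfg <- crosslink_config(n_age = 1, ecl_content = 25)
  expect_error(insert_ages(fib, cfg, strict = TRUE), "before equilibration")
  expect_error(insert_ecl(fib, cfg, strict = TRUE), "before equilibration")
})

test_that("cross-link sets round-trip through the plain-text table", {
  fib <- cached_mini_minimized()
  cfg <- crosslink_config(ecl_content = 50, n_age = 2, seed = 31)
  out <- insert_ages(insert_ecl(fib, cfg), cfg)
  tf <- tempfile(fileext = ".tsv")
  write_crosslinks(out, tf)
  re <- apply_crosslinks(fib, tf)
  expect_equal(re$topology$bonds[order(re$topology$bonds$i, re$topology$bonds$j), ],
               out$topology$bonds[order(out$topology$bonds$i, out$topology$bonds$j), ],
               ignore_attr = TRUE)
})
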