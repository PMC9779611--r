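test_that("detect_bonds applies the 3 A SG-SG cutoff", {
  one <- parse_pdb_lines(make_cys_structure(list(c(1, 2, 2.05)), 2,
                                            seed = 1))
  t1 <- detect_bonds(one)
  expect_equal(nrow(t1$bonds), 1L)
  expect_equal(t1$bonds$distance, 2.05, tolerance = 1e-6)
  expect_equal(nrow(t1$free), 0L)

  far <- parse_pdb_lines(make_cys_structure(list(c(1, 2, 3.20)), 2,
                                            seed = 1))
  t2 <- detect_bonds(far)
  expect_equal(nrow(t2$bonds), 0L)
  expect_equal(nrow(t2$free), 2L)
  # boundary is strict: exactly at the cutoff is not a bond
  at <- parse_pdb_lines(make_cys_structure(list(c(1, 2, 3.0)), 2,
                                           seed = 1))
  expect_equal(nrow(detect_bonds(at)$bonds), 0L)
  expect_equal(nrow(detect_bonds(at, cutoff_angstrom = 3.01)$bonds), 1L)
})

test_that("the 7-cysteine fixture yields the expected pattern", {
  pdb <- make_cys_structure(list(c(1, 6, 2.05), c(2, 4, 2.05),
                                 c(3, 5, 2.05)), 7, seed = 42)
  topo <- detect_bonds(parse_pdb_lines(pdb))
  expect_equal(notation_dash(topo), "C1-C6, C2-C4, C3-C5")
  expect_equal(notation_pipe(topo), "|C:1 C:6 |C:2 C:4 |C:3 C:5")
  expect_equal(topo$free$ordinal, 7L)   # the reactive C-terminal cys
})

test_that("greedy conflict resolution takes ascending distances", {
  # three SG sites on a line: d(1,2)=2.0, d(2,3)=2.9 -> bond (1,2), 3 free
  ca <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  sg <- list(`1` = c(0, 2, 0), `2` = c(2, 2, 0), `3` = c(4.9, 2, 0))
  m <- tickfold:::model_from_ca(ca, "CCC", sg = sg)
  topo <- detect_bonds(m)
  expect_equal(nrow(topo$bonds), 1L)
  expect_equal(sort(c(topo$bonds$ordinal_a, topo$bonds$ordinal_b)),
               c(1L, 2L))
  expect_equal(topo$free$ordinal, 3L)
  # chain of four SGs at gaps 2.8/2.0/2.8: greedy grabs the middle pair
  # and strands the ends; maxweight finds the two-bond matching
  sg2 <- list(`1` = c(0, 2, 0), `2` = c(2.8, 2, 0), `3` = c(4.8, 2, 0),
              `4` = c(7.6, 2, 0))
  m2 <- tickfold:::model_from_ca(rbind(ca, c(12, 0, 0)), "CCCC",
                                 sg = sg2)
  greedy <- detect_bonds(m2)
  mw <- detect_bonds(m2, method = "maxweight")
  expect_equal(nrow(greedy$bonds), 1L)
  expect_equal(nrow(mw$bonds), 2L)
})

test_that("conservation: 2*bonds + free == SG-bearing cysteines", {
  with_seed(303, {
    for (rep in 1:25) {
      n_cys <- sample(2:10, 1)
      pairs <- random_topology_spec(n_cys)
      pdb <- make_cys_structure(pairs, n_cys, seed = sample(1e6, 1))
      topo <- detect_bonds(parse_pdb_lines(pdb))
      n_sg <- sum(topo$sites$has_sg)
      expect_equal(2L * nrow(topo$bonds) + sum(topo$free$has_sg), n_sg)
      expect_equal(nrow(topo$bonds), length(pairs))
    }
  })
})

test_that("detect_bonds is invariant under rigid motion", {
  pdb <- make_cys_structure(list(c(1, 4, 2.05), c(2, 5, 2.2)), 6,
                            seed = 8)
  m <- parse_pdb_lines(pdb)
  t0 <- detect_bonds(m)
  set.seed(12)
  for (rep in 1:5) {
    mt <- rigid_motion_model(m, random_rotation(), rnorm(3, sd = 30))
    tt <- detect_bonds(mt)
    expect_equal(notation_dash(tt), notation_dash(t0))
    expect_equal(tt$bonds$distance, t0$bonds$distance, tolerance = 1e-6)
  }
})

test_that("raising the cutoff never removes a bond", {
  with_seed(99, {
    for (rep in 1:10) {
      n_cys <- sample(3:8, 1)
      pdb <- make_cys_structure(random_topology_spec(n_cys), n_cys,
                                seed = sample(1e6, 1))
      m <- parse_pdb_lines(pdb)
      prev <- -1L
      for (cut in c(1.5, 2.5, 3.0, 5.0)) {
        nb <- nrow(detect_bonds(m, cut)$bonds)
        expect_gte(nb, prev)
        prev <- nb
      }
    }
  })
})

test_that("parse_notation handles dash, en-dash, pipe and chains", {
  knottin <- parse_notation("C1–C4, C2–C5, C3–C6")
  expect_equal(knottin$ordinal_a, c(1L, 2L, 3L))
  expect_equal(knottin$ordinal_b, c(4L, 5L, 6L))
  pipe <- parse_notation("|C:1 C:3 |C:2 C:5 |C:4 C:6")
  expect_equal(pipe$ordinal_a, c(1L, 2L, 4L))
  expect_equal(pipe$ordinal_b, c(3L, 5L, 6L))
  seven <- parse_notation(
    "C1-C5, C2-C4, C3-C13, C6-C14, C7-C10, C8-C12, C9-C11")
  expect_equal(nrow(seven), 7L)
  expect_equal(max(seven$ordinal_b), 14L)
  inter <- parse_notation("A:1|B:8, A:8|B:1")
  expect_equal(inter$chain_a, c("A", "A"))
  expect_equal(inter$ordinal_b, c(8L, 1L))
  expect_error(parse_notation("C1-C2, C1-C3"), "more than one")
  expect_error(parse_notation("C1~C2"), "malformed")
  expect_error(parse_notation("|C:1 C:2 |C:x C:4"), "malformed")
})

test_that("notation round-trips the detected bond set", {
  with_seed(71, {
    for (rep in 1:20) {
      n_cys <- sample(2:12, 1)
      pairs <- random_topology_spec(n_cys)
      topo <- detect_bonds(parse_pdb_lines(
        make_cys_structure(pairs, n_cys, seed = sample(1e6, 1))))
      want <- tickfold:::topology_bondset(topo)
      if (nrow(want) == 0L) next
      expect_equal(parse_notation(notation_dash(topo)), want)
      expect_equal(parse_notation(notation_pipe(topo)), want)
    }
  })
})

test_that("consensus_topology counts support and recovers patterns", {
  base <- make_cys_structure(list(c(1, 4, 2.05), c(2, 5, 2.05),
                                  c(3, 6, 2.05)), 6, seed = 7)
  topos <- lapply(1:5, function(i) detect_bonds(parse_pdb_lines(base)))
  cons <- consensus_topology(topos)
  expect_equal(cons$consensus,
               data.frame(ordinal_a = 1:3, ordinal_b = 4:6))
  expect_true(all(cons$support$support == 1.0))

  broken <- make_cys_structure(list(c(1, 4, 3.4), c(2, 5, 2.05),
                                    c(3, 6, 2.05)), 6, seed = 7)
  topos10 <- c(lapply(1:9, function(i) {
    detect_bonds(parse_pdb_lines(base))
  }), list(detect_bonds(parse_pdb_lines(broken))))
  cons10 <- consensus_topology(topos10)
  s14 <- cons10$support$support[cons10$support$ordinal_a == 1L]
  expect_equal(s14, 0.9)

  # parameter recovery from jittered models
  fam <- make_family(base, n = 10, sigma = 0.3, seed = 5)
  consj <- consensus_topology(lapply(fam, parse_pdb_lines))
  expect_equal(consj$consensus,
               data.frame(ordinal_a = 1:3, ordinal_b = 4:6))
  expect_error(consensus_topology(topos[1]), ">= 2")
})

test_that("dimer_bridge_scan reports inter-chain bonds and symmetry", {
  homo <- parse_pdb_lines(make_homodimer(7, 7))
  sc <- dimer_bridge_scan(homo)
  expect_equal(sc$notation, "A:7|B:7")
  expect_true(sc$symmetric_dimer)
  # conservation across the multimer
  topo <- detect_bonds(homo)
  expect_equal(2L * nrow(topo$bonds) + sum(topo$free$has_sg),
               sum(topo$sites$has_sg))

  recip <- parse_pdb_lines(make_dimer(bridges = rbind(c(1, 8), c(8, 1)),
                                      n_cys = 8))
  sr <- dimer_bridge_scan(recip)
  expect_equal(nrow(sr$interchain), 2L)
  expect_true(all(sr$interchain$symmetric))
  expect_true(sr$symmetric_dimer)

  mono <- parse_pdb_lines(make_cys_structure(list(c(1, 2, 2.05)), 2,
                                             seed = 3))
  expect_equal(nrow(dimer_bridge_scan(mono)$interchain), 0L)
})

test_that("cysteines without SG are counted free with a warning", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
              c(11.4, 0, 0), c(15.2, 0, 0))
  sg <- list(`2` = c(3.8, 2, 0), `4` = c(4.8, 2, 0))  # cys 1 has no SG
  m <- tickfold:::model_from_ca(ca, "CCACA", sg = sg)
  expect_warning(topo <- detect_bonds(m), "lack an SG")
  expect_equal(nrow(topo$bonds), 1L)
  expect_true(any(!topo$free$has_sg))
  # no cysteines at all: empty topology, not an error
  m2 <- tickfold:::model_from_ca(ca, "AAAAA")
  expect_equal(nrow(detect_bonds(m2)$sites), 0L)
})
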