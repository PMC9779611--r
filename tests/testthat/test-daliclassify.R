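hit_row <- function(query = "q1", target = "4q1l-A", z = 12, rmsd = 2.5,
                    lali = 100, pct_id = 10, desc = "metalloprotease") {
  data.frame(query_id = query, target_pdb = target, z = z, rmsd = rmsd,
             lali = lali, pct_id = pct_id, description = desc,
             stringsAsFactors = FALSE)
}

test_that("zband implements the half-open manual intervals", {
  expect_equal(zband(21.0), "homologous")
  expect_equal(zband(14.8), "probably_homologous")
  expect_equal(zband(1.5), "not_significant")
  # boundaries belong to the stronger band
  expect_equal(zband(c(20, 8, 2)),
               c("homologous", "probably_homologous", "gray"))
  expect_equal(zband(7.4), "gray")
  expect_error(zband(NaN), "non-finite")
  expect_error(zband(Inf), "non-finite")
})

test_that("zband is total and monotone", {
  with_seed(5, {
    z <- sort(runif(200, -5, 40))
    r <- tickfold:::band_rank(zband(z))
    expect_true(all(!is.na(r)))
    expect_true(all(diff(r) >= 0))
  })
})

test_that("best_hit maximises z with rmsd and id tie-breaks", {
  hits <- rbind(hit_row(z = 14.8), hit_row(z = 7.4, target = "1abc-A"))
  expect_equal(best_hit(hits)$z, 14.8)
  tie <- rbind(hit_row(z = 10, rmsd = 3.0, target = "2bbb-A"),
               hit_row(z = 10, rmsd = 2.1, target = "1aaa-A"))
  expect_equal(best_hit(tie)$rmsd, 2.1)
  tie2 <- rbind(hit_row(z = 10, rmsd = 2.1, target = "2bbb-A"),
                hit_row(z = 10, rmsd = 2.1, target = "1aaa-A"))
  expect_equal(best_hit(tie2)$target_pdb, "1aaa-A")
  expect_equal(best_hit(hit_row()), hit_row())
  expect_error(best_hit(hit_row()[0, ]), "no hits")
})

test_that("metalloproteoid vs metalloprotease flips on the zinc motif", {
  rec <- seq_record("q1", "MKAAAA", family = "28 kDa")
  hits <- hit_row(z = 12)
  no_motif <- classify(rec, hits, motif_hits = NULL)
  expect_equal(no_motif$new_group, "Metalloproteoid")
  expect_equal(no_motif$rule_id, "R1")
  expect_equal(no_motif$new_subgroup, "28 kDa")
  mh <- data.frame(pattern_id = "ZINC_BINDING", record_id = "q1",
                   start = 3L, end = 13L, matched = "HEAAHAAGAAH",
                   stringsAsFactors = FALSE)
  with_motif <- classify(rec, hits, motif_hits = mh)
  expect_equal(with_motif$new_group, "Metalloprotease")
  expect_equal(with_motif$rule_id, "R2")
  # motif hits for a different record do not leak in
  mh_other <- transform(mh, record_id = "q2")
  expect_equal(classify(rec, hits, mh_other)$new_group,
               "Metalloproteoid")
})

test_that("category rules fire at their per-family Z floors", {
  rec <- seq_record("q1", "MKAAAA")
  tox <- classify(rec, hit_row(target = "3zjx-A", z = 12,
                               desc = "EPSILON-TOXIN"))
  expect_equal(tox$new_group, "Cytotoxin")
  expect_equal(tox$rule_id, "R3")
  derf <- classify(rec, hit_row(target = "5wcx-A", z = 10.5,
                                desc = "Der f 7 allergen"))
  expect_equal(derf$new_group, "Der f 7 allergen/JHBP")
  np <- classify(rec, hit_row(target = "1nep-A", z = 12.5,
                              desc = "Niemann-Pick C2 protein"))
  expect_equal(np$new_group, "Niemann-Pick")
  # below its floor the same category falls through
  np_low <- classify(rec, hit_row(target = "1nep-A", z = 11,
                                  desc = "Niemann-Pick C2 protein"))
  expect_equal(np_low$new_group, "no significant structural match")
  lip <- classify(rec, hit_row(target = "1qft-A", z = 13,
                               desc = "histamine-binding lipocalin"))
  expect_equal(lip$new_group, "Lipocalin")
  expect_equal(lip$new_subgroup, "unspecified")  # no old family label
  none <- classify(rec, NULL)
  expect_equal(none$new_group, "no significant structural match")
  expect_equal(none$rule_id, "R7")
})

test_that("classification partitions the 137-row scenario", {
  scn <- make_partition_scenario(seed = 1)
  tab <- classify_batch(scn$records, scn$hits)
  expect_equal(nrow(tab), 137L)
  counts <- table(tab$new_group)
  expect_equal(unname(counts[["Der f 7 allergen/JHBP"]]), 94L)
  expect_equal(unname(counts[["Cytotoxin"]]), 32L)
  expect_equal(unname(counts[["Sulfotransferase"]]), 2L)
  expect_equal(unname(counts[["no significant structural match"]]), 9L)
  expect_equal(sum(counts), 137L)   # partition property
  # deterministic and replayable
  expect_identical(tab, classify_batch(scn$records, scn$hits))
})

test_that("dali tables parse in strict and lenient dialects", {
  scn <- make_partition_scenario(seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  make_dali_table(scn$hits, f)
  strict <- read_dali_table(f)
  expect_equal(nrow(strict), 137L)
  expect_equal(strict$z, scn$hits$z)
  # lenient whitespace dialect (descriptions collapse to single spaces)
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%s  %s  %.1f %.1f %d %.1f %s",
                     scn$hits$query_id, scn$hits$target_pdb, scn$hits$z,
                     scn$hits$rmsd, scn$hits$lali, scn$hits$pct_id,
                     scn$hits$description), g)
  lenient <- read_dali_table(g)
  expect_equal(lenient$z, strict$z)
  expect_equal(lenient$target_pdb, strict$target_pdb)
  writeLines("q1\tonly", f)
  expect_error(read_dali_table(f), "lacks column")
  writeLines("q1 2abc-A", g)
  expect_error(read_dali_table(g), "malformed")
})

test_that("target categorisation prefers PDB ids over keywords", {
  # 2d42-A's description says nothing toxin-like, the id decides
  h <- hit_row(target = "2d42-A", desc = "NON-TOXIC CRYSTAL PROTEIN")
  expect_equal(target_category(h), "bacterial_pore_toxin")
  expect_equal(target_category(hit_row(desc = "snake adamalysin")),
               "metalloprotease")
  expect_equal(target_category(hit_row(target = "9zzz-A",
                                       desc = "mystery protein")),
               "other")
})

test_that("rename_motif applies the static ledger", {
  expect_equal(rename_motif("40-800"), "Kunitz")
  expect_equal(rename_motif("40-584"), "acid tail")
  expect_equal(rename_motif("35-53"), "Lipocalin")
  expect_equal(rename_motif("Rapp-25-325"), "cystatin")
  expect_equal(rename_motif("25-159"), "Cytochrome_B2")
  for (id in c("30-49", "30-561", "30-93", "35-121", "35-167", "35-414",
               "35-415", "35-768", "35-77", "50-341")) {
    expect_equal(rename_motif(id), "Metalloproteoid")
  }
  expect_message(out <- rename_motif("99-999"), "not in rename ledger")
  expect_equal(out, "99-999")
})
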