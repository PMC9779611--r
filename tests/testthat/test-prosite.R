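test_that("compile_pattern produces faithful element lists", {
  zinc <- compile_pattern("H-E-x(2)-H-x(2)-G-x(2)-H")
  lens <- vapply(zinc$elements, function(e) e$max, 1L)
  expect_equal(sum(lens), 11L)  # 11-position pattern
  types <- rep(vapply(zinc$elements, `[[`, "", "type"), lens)
  expect_equal(which(types == "any"), c(3L, 4L, 6L, 7L, 9L, 10L))

  p450 <- compile_pattern("[AG]-G-x-[ED]-T")
  expect_length(p450$elements, 5L)
  expect_equal(p450$elements[[1]],
               list(type = "set", residues = "AG", min = 1L, max = 1L))
  expect_equal(p450$elements[[4]]$residues, "ED")

  anch <- compile_pattern("<M-x(2,4)-{P}>")
  expect_true(anch$anchor_n && anch$anchor_c)
  expect_equal(anch$elements[[2]]$min, 2L)
  expect_equal(anch$elements[[2]]$max, 4L)
  expect_equal(anch$elements[[3]]$type, "exclude")
})

test_that("compile_pattern rejects malformed syntax with position info", {
  expect_error(compile_pattern("x(2,"), "element 1")
  expect_error(compile_pattern("A-[BZ"), "malformed element")
  expect_error(compile_pattern("A-x(0)"), "invalid repeat")
  expect_error(compile_pattern("A-x(4,2)"), "invalid repeat")
  expect_error(compile_pattern("A-J"), "unknown residue")
  expect_error(compile_pattern(""), "empty")
})

test_that("scan_sequence matches the zinc-binding motif semantics", {
  zinc <- motif_library(include_disintegrin = FALSE)$ZINC_BINDING
  h <- scan_sequence(zinc, "AAHEAAHAAGAAHAA", "t")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)
  expect_equal(h$end, 13L)
  expect_equal(h$matched, "HEAAHAAGAAH")
  # E->Q at position 4 kills the fixed position
  expect_equal(nrow(scan_sequence(zinc, "AAHQAAHAAGAAHAA", "t")), 0L)
  # masked residue rule: specific letter never matches X, wildcard does
  expect_equal(nrow(scan_sequence(zinc, "AAHEXXHXXGXXHAA", "t")), 1L)
  expect_equal(nrow(scan_sequence(zinc, "AAXEAAHAAGAAHAA", "t")), 0L)
})

test_that("scanner agrees with the brute-force oracle on random input", {
  pats <- list(compile_pattern("R-G-D", "RGD"),
               compile_pattern("[AG]-G-x-[ED]-T", "P450_CATALYTIC"),
               compile_pattern("H-E-x(2)-H-x(2)-G-x(2)-H", "ZINC"),
               compile_pattern("C-x(0,5)-R-G-D", "FLANK"),
               compile_pattern("<M-x(1,3)-K", "NANCH"),
               compile_pattern("G-{P}-x-C>", "CANCH"))
  n_cases <- 0L
  with_seed(2024, {
    # a biased alphabet so motifs actually occur
    alpha <- c(AA20, strsplit("RGDAGETHECKM", "")[[1]])
    for (rep in 1:180) {
      seqs <- paste(sample(alpha, sample(5:50, 1), replace = TRUE),
                    collapse = "")
      for (p in pats) {
        got <- scan_sequence(p, seqs, "q")
        want <- oracle_scan(p, seqs)
        expect_identical(got$start, want$start)
        expect_identical(got$end, want$end)
        expect_identical(got$matched, want$matched)
        n_cases <- n_cases + 1L
      }
    }
  })
  expect_gte(n_cases, 1000L)
})

test_that("hit substrings re-match their own pattern (idempotence)", {
  pats <- list(compile_pattern("C-x(0,5)-R-G-D", "FLANK"),
               compile_pattern("[AG]-G-x-[ED]-T", "CAT"))
  total <- 0L
  with_seed(7, {
    for (rep in 1:50) {
      seqs <- paste(sample(c(AA20, strsplit("RGDC", "")[[1]]),
                           sample(10:60, 1), replace = TRUE),
                    collapse = "")
      # guarantee some hits: splice a motif core into half the cases
      if (rep %% 2L == 0L) {
        ins <- sample(c("CAARGD", "AGGAET"), 1)
        at <- sample(nchar(seqs), 1)
        seqs <- paste0(substr(seqs, 1, at), ins,
                       substr(seqs, at + 1L, nchar(seqs)))
      }
      for (p in pats) {
        h <- scan_sequence(p, seqs, "q")
        for (m in h$matched) {
          again <- scan_sequence(p, m, "sub")
          expect_true(any(again$start == 1L & again$end == nchar(m)))
          total <- total + 1L
        }
      }
    }
  })
  expect_gte(total, 25L)
})

test_that("scanning is translation invariant under a neutral prefix", {
  p <- compile_pattern("R-G-D", "RGD")
  zinc <- compile_pattern("H-E-x(2)-H-x(2)-G-x(2)-H", "ZINC")
  with_seed(13, {
    for (rep in 1:30) {
      seqs <- paste(sample(c(AA20, "R", "G", "D", "H", "E"),
                           sample(10:40, 1), replace = TRUE),
                    collapse = "")
      k <- sample(1:10, 1)
      for (pat in list(p, zinc)) {
        base <- scan_sequence(pat, seqs, "q")
        shifted <- scan_sequence(pat, paste0(strrep("P", k), seqs), "q")
        # "P" can extend a wildcard window across the boundary for ZINC
        # only if an H sits at position 1; exclude those rare layouts
        shifted <- shifted[shifted$start > k, , drop = FALSE]
        expect_equal(shifted$start, base$start + k)
        expect_equal(shifted$end, base$end + k)
      }
    }
  })
})

test_that("scan_database flags records and sorts hits", {
  recs <- list(seq_record("a", "MKAAAA"), seq_record("b", "MKRGDAA"),
               seq_record("c", "MKAAAA"))
  res <- scan_database(disintegrin_blocks(), recs)
  expect_equal(sum(res$flagged), 1L)
  expect_true(res$flagged[["b"]])
  expect_equal(nrow(scan_database(list(), recs)$hits), 0L)
  expect_false(any(scan_database(list(), recs)$flagged))
  # sorted by record then start
  many <- list(seq_record("z", "RGDAARGD"), seq_record("a", "KGDRGD"))
  hits <- scan_database(disintegrin_blocks(), many)$hits
  expect_equal(hits$record_id, sort(hits$record_id))
  expect_true(all(diff(hits$start[hits$record_id == "z"]) >= 0))
})

test_that("the shipped disintegrin block file loads and scans", {
  path <- system.file("extdata", "disintegrin_blocks.prosite",
                      package = "tickfold")
  lib <- read_prosite_file(path)
  expect_true(all(c("DISINTEGRIN_RGD", "DISINTEGRIN_RED",
                    "DISINTEGRIN_RGD_CFLANK") %in% names(lib)))
  # the flanked block needs the cysteine pair, the bare triad does not
  hit <- scan_database(lib["DISINTEGRIN_RGD_CFLANK"],
                       list(seq_record("y", "AACAARGDAACAA")))
  miss <- scan_database(lib["DISINTEGRIN_RGD_CFLANK"],
                        list(seq_record("n", "AAAAARGDAAAAA")))
  expect_true(hit$flagged[["y"]])
  expect_false(miss$flagged[["n"]])
  expect_true(scan_database(lib["DISINTEGRIN_RGD"],
                            list(seq_record("n", "AAAAARGDAAAAA")))$flagged)
})

test_that("P450 built-ins match constructed positives and negatives", {
  lib <- motif_library(include_disintegrin = FALSE)
  # heme pocket: F-x-x-G-x-[HR]-x-C-x-G
  pos <- "AAFGAGAHACAGAA"
  expect_equal(nrow(scan_sequence(lib$P450_HEME, pos, "p")), 1L)
  neg <- sub("C", "S", pos)   # lose the heme-ligating cysteine
  expect_equal(nrow(scan_sequence(lib$P450_HEME, neg, "n")), 0L)
  # catalytic: [AG]-G-x-[ED]-T
  expect_equal(nrow(scan_sequence(lib$P450_CATALYTIC, "KAGGAETAK", "p")),
               1L)
  expect_equal(nrow(scan_sequence(lib$P450_CATALYTIC, "KAGGAKTAK", "n")),
               0L)
})
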