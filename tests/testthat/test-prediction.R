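ss2_fixture <- function() {
  paste(
    "# ss2-style prediction table",
    "1 M C 0.998 0.001 0.001",
    "2 K H 0.100 0.850 0.050",
    "3 V H 0.150 0.800 0.050",
    "4 I E 0.100 0.100 0.800",
    "5 L C 0.600 0.200 0.200",
    sep = "\n"
  )
}

tsv_fixture <- function() {
  paste(
    "index residue helix strand coil disorder",
    "1 M 0.1 0.1 0.8 0.2",
    "2 K 0.9 0.05 0.05 0.95",
    "3 V 0.5 0.2 0.3 0.7",
    sep = "\n"
  )
}

test_that("ss2 tables parse with the fixed coil/helix/strand column order", {
  tr <- parse_ss_prediction(ss2_fixture())
  expect_equal(nrow(tr), 5)
  expect_equal(tr$residue, c("M", "K", "V", "I", "L"))
  expect_equal(tr$helix[2], 0.85)
  expect_equal(tr$strand[4], 0.80)
  expect_equal(tr$coil[1], 0.998)
  expect_true(all(is.na(tr$disorder)))
})

test_that("the TSV dialect parses named headers and normalizes disorder", {
  tr <- parse_ss_prediction(tsv_fixture())
  expect_equal(tr$helix, c(0.1, 0.9, 0.5))
  # 0-1 disorder becomes floor(10 x conf) capped at 9
  expect_equal(tr$disorder, c(2L, 9L, 7L))
})

test_that("prediction tracks are cross-checked against the sequence", {
  expect_silent(parse_ss_prediction(ss2_fixture(), "MKVIL"))
  expect_error(parse_ss_prediction(ss2_fixture(), "MKVIR"),
               "track-mismatch error at residue 5")
  expect_error(parse_ss_prediction(ss2_fixture(), "MKVI"),
               "track-mismatch")
  expect_error(parse_ss_prediction("1 M C 0.9 0.1"), "fewer than 6")
  expect_error(parse_ss_prediction(
    "index residue helix strand\n1 M 0.5 0.5"), "lacks column")
})

test_that("render classes switch exactly at 0.3 and 0.7", {
  expect_equal(ss_render_class(0.8, 0.1), "strong-helix")
  expect_equal(ss_render_class(0.1, 0.5), "weak-strand")
  expect_equal(ss_render_class(0.2, 0.2), "none")
  expect_equal(ss_render_class(0.5, 0.5), "none")   # exact tie
  grid <- (0:100) / 100
  cls <- ss_render_class(grid, 0)
  changes <- grid[which(cls[-1] != cls[-length(cls)]) + 1]
  expect_equal(changes, c(0.3, 0.7))
  expect_equal(cls[grid == 0.7], "strong-helix")
  expect_equal(cls[grid == 0.3], "weak-helix")
})

test_that("disorder renders at confidence >= 8", {
  expect_true(disorder_render_class(8))
  expect_false(disorder_render_class(7))
  expect_true(disorder_render_class(9))
  expect_equal(which(disorder_render_class(0:9)) - 1, c(8, 9))
})

test_that("only the first sequence row plus all model rows get predictions", {
  mk <- function(roles) {
    new_alignment(lapply(seq_along(roles), function(i)
      aligned_sequence(paste0("s", i), roles[i], "ACDE")))
  }
  expect_equal(select_predicted_sequences(
    mk(c("structure", "sequence", "sequence"))), "s2")
  expect_equal(select_predicted_sequences(mk(c("model", "sequence"))),
               c("s1", "s2"))
  expect_equal(select_predicted_sequences(mk(c("structure", "structure"))),
               character(0))
})
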