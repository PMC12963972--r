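test_that("matrix round-trip is lossless for integer counts", {
  set.seed(7)
  profs <- lapply(1:3, function(i)
    mutation_profile(paste0("s", i), rpois(96, 20), sbs96))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(profs, path)
  back <- read_matrix(path)
  expect_named(back, c("s1", "s2", "s3"))
  for (i in 1:3) {
    expect_identical(back[[i]]$schema$name, "SBS96")
    expect_identical(unname(back[[i]]$counts), unname(profs[[i]]$counts))
  }
})

test_that("row order in the file is normalized to the canonical schema order", {
  set.seed(8)
  prof <- mutation_profile("s", rpois(96, 5), sbs96)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(MutationType = sbs96$labels, s = as.numeric(prof$counts))
  perm <- sample(96)
  utils::write.table(df[perm, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_matrix(path)[[1]]
  expect_identical(unname(back$counts), unname(prof$counts))
  expect_identical(names(back$counts), sbs96$labels)
})

test_that("schema errors name the offending labels", {
  df <- data.frame(MutationType = sbs96$labels[-5], s = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matrix(path, schema_hint = "SBS96"),
               sbs96$labels[5], fixed = TRUE)
  df2 <- data.frame(MutationType = c(sbs96$labels, "bogus"), s = 1)
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matrix(path, schema_hint = "SBS96"), "bogus")
})

test_that("negative and malformed values are parse errors with location", {
  df <- data.frame(MutationType = sbs96$labels, s = 1)
  df$s[10] <- -3
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matrix(path), "negative|missing")
})

test_that("normalize divides by burden and rejects empty profiles", {
  sch <- tiny_schema(4)
  p <- mutation_profile("a", c(2, 2, 0, 0), sch)
  sig <- normalize(p)
  expect_equal(unname(sig$proportions), c(0.5, 0.5, 0, 0))
  flat <- normalize(mutation_profile("b", rep(3, 4), sch))
  expect_equal(unname(flat$proportions), rep(0.25, 4))
  expect_error(normalize(mutation_profile("z", rep(0, 4), sch)),
               "zero burden")
})

test_that("weighted profile weights samples by mutation burden", {
  sch <- tiny_schema(4)
  p1 <- mutation_profile("a", c(80, 10, 5, 5), sch)   # burden 100
  p2 <- mutation_profile("b", c(30, 90, 90, 90), sch) # burden 300
  w <- weighted_profile(list(p1, p2))
  expect_equal(unname(w$counts), unname(0.25 * p1$counts + 0.75 * p2$counts))
  expect_true(w$weighted)

  # single profile is unchanged; n copies collapse to the original
  expect_equal(unname(weighted_profile(list(p1))$counts), unname(p1$counts))
  expect_equal(unname(weighted_profile(list(p2, p2, p2))$counts),
               unname(p2$counts))

  # equal burdens average the counts
  p3 <- mutation_profile("c", c(10, 20, 30, 40), sch)
  p4 <- mutation_profile("d", c(40, 30, 20, 10), sch)
  expect_equal(unname(weighted_profile(list(p3, p4))$counts),
               unname((p3$counts + p4$counts) / 2))
})

test_that("normalized weighted profile equals the burden-weighted mean of signatures", {
  set.seed(11)
  sch <- tiny_schema(6)
  profs <- lapply(1:4, function(i)
    mutation_profile(paste0("s", i), rpois(6, 30) + 1, sch))
  w <- normalize(weighted_profile(profs))
  tmb <- vapply(profs, `[[`, numeric(1), "burden")
  # sum(w_i * m_i) = sum(w_i * TMB_i * n_i), so after normalization the
  # signature is the mean of the normalized profiles weighted by w_i * TMB_i
  manual <- Reduce(`+`, Map(function(p, wi) wi * normalize(p)$proportions,
                            profs, tmb^2 / sum(tmb^2)))
  expect_equal(unname(w$proportions), unname(manual / sum(manual)),
               tolerance = 1e-12)
})

test_that("weighted (real-valued) profiles survive a write/read round trip", {
  sch <- tiny_schema(5)
  p <- mutation_profile("w", c(1.25, 2.5, 0.125, 7.375, 3.2), sch,
                        weighted = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(list(p), path)
  back <- read_matrix(path, schema_hint = "CUSTOM")[[1]]
  expect_equal(unname(back$counts), unname(p$counts), tolerance = 1e-9)
})

test_that("mixed schemas and empty input are rejected", {
  a <- mutation_profile("a", rep(1, 4), tiny_schema(4))
  b <- mutation_profile("b", rep(1, 5), tiny_schema(5))
  expect_error(weighted_profile(list(a, b)), "schema mismatch")
  expect_error(write_matrix(list(), tempfile()), "nothing to write")
  expect_error(weighted_profile(list()), "no profiles")
})
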