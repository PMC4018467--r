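test_that("tandem amplification obeys its length law", {
  expect_identical(tandem("GA", 3), "GAGAGA")
  expect_identical(tandem("ACGT", 1), "ACGT")
  set.seed(8)
  for (i in 1:20) {
    s <- random_dna(sample(1:50, 1))
    expect_equal(nchar(tandem(s, 100)), 100 * nchar(s))
  }
  expect_error(tandem("", 2))
  expect_error(tandem("A", 0))
})

test_that("compressing empty input yields the 3-byte .Z header", {
  z <- compress_lzw(raw(0))
  expect_identical(z, as.raw(c(0x1F, 0x9D, 0x90)))
  expect_identical(decompress_lzw(z), raw(0))
})

test_that("coder round-trips arbitrary byte strings and matches the independent decoders", {
  set.seed(2024)
  sizes <- c(0, 1, 2, 3, 10, 100, 511, 512, 1000, 5000, 10000)
  for (i in 1:60) {
    n <- sample(sizes, 1)
    x <- switch(i %% 3 + 1,
                as.raw(sample(0:255, n, replace = TRUE)),
                charToRaw(strrep("GA", ceiling(n / 2)))[seq_len(n)],
                charToRaw(random_dna(max(n, 1)))[seq_len(n)])
    z <- compress_lzw(x)
    expect_identical(decompress_lzw(z), x)
    expect_identical(lzw_oracle_decompress(z), x)
  }
  # reference system decoder understands our streams
  x <- charToRaw(tandem("TCTCACGAGAGACTGAGAGA", 100))
  expect_identical(reference_uncompress(compress_lzw(x)), x)
})

test_that("the dictionary-reset (CLEAR) path round-trips through the reference decoder", {
  set.seed(31)
  x <- as.raw(sample(0:255, 400000, replace = TRUE))
  z <- compress_lzw(x)
  expect_identical(decompress_lzw(z), x)
  expect_identical(reference_uncompress(z), x)
})

test_that("decompressing non-.Z input raises a format error", {
  expect_error(decompress_lzw(as.raw(c(0x00, 0x01, 0x02))), "magic")
  expect_error(decompress_lzw(charToRaw("GAGAGA")), "magic")
})

test_that("repetitive sequences compress better than shuffled ones of equal length", {
  set.seed(55)
  pure <- strrep("GA", 150)
  b_pure <- length(compress_lzw(tandem(pure, 100)))
  chars <- strsplit(pure, "")[[1]]
  for (i in 1:20) {
    shuf <- paste(sample(chars), collapse = "")
    expect_lt(b_pure, length(compress_lzw(tandem(shuf, 100))))
  }
})

test_that("compressed size is monotone over nested prefixes and sub-additive under tandem", {
  set.seed(66)
  s <- random_dna(600)
  sizes <- vapply(c(100, 200, 400, 600), function(k) {
    length(compress_lzw(substr(s, 1, k)))
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))

  for (i in 1:5) {
    rep_seq <- paste0(random_dna(10), strrep("GA", 40), random_dna(10))
    b100 <- length(compress_lzw(tandem(rep_seq, 100)))
    b10 <- length(compress_lzw(tandem(rep_seq, 10)))
    b1 <- length(compress_lzw(rep_seq))
    expect_lt(b100, 100 * b1)
    expect_lte(b100, 5 * b10)
  }
})

test_that("panel profiles are deterministic and identical sequences share B", {
  seqs <- c(a = "GAGAGAGAGA", b = "GAGAGAGAGA", c = "TTTCCCGGAA")
  prof <- profile_panel(seqs, tandem_factor = 50)
  expect_equal(prof$B[1], prof$B[2])
  expect_equal(prof$L, c(10L, 10L, 10L))
  prof2 <- profile_panel(seqs, tandem_factor = 50)
  expect_identical(as.data.frame(prof), as.data.frame(prof2))
})

test_that("size-mode distances collapse to |B_i - B_j| under every metric", {
  prof <- structure(
    data.frame(id = c("lo", "hi"), L = c(66L, 761L),
               tandem_factor = 100L, B = c(734L, 7249L)),
    payloads = list(lo = as.raw(1:10), hi = as.raw(1:12)),
    class = c("compression_profile", "data.frame")
  )
  for (metric in c("euclidean", "maximum", "manhattan")) {
    d <- distance_matrix(prof, metric = metric)
    expect_equal(as.numeric(d), 6515)
  }
})

test_that("distances are metrics: zero diagonal, symmetry, and exact scalar-mode equality", {
  p <- generate_panel(panel_config(seed = 6L))
  prof <- profile_panel(p)
  d_man <- as.matrix(distance_matrix(prof, "manhattan"))
  d_euc <- as.matrix(distance_matrix(prof, "euclidean"))
  d_max <- as.matrix(distance_matrix(prof, "maximum"))
  expect_identical(d_man, d_euc)
  expect_identical(d_man, d_max)
  expect_true(all(diag(d_man) == 0))
  expect_identical(d_man, t(d_man))
  expect_true(all(d_man >= 0))
})

test_that("byte-vector mode matches a naive double-loop L1 oracle", {
  seqs <- setNames(
    c("GAGAGAGAGAGA", "GAGACTGAGAGA", "TTACGCATGACA", "GACTGACTGACT",
      "AAAAAAAAAAAA"),
    paste0("s", 1:5)
  )
  prof <- profile_panel(seqs, tandem_factor = 20)
  d <- as.matrix(distance_matrix(prof, "manhattan", mode = "byte_vector"))
  payloads <- attr(prof, "payloads")
  width <- max(vapply(payloads, length, integer(1))) - 3L
  padded <- lapply(payloads, function(p) {
    v <- as.integer(p[-(1:3)])
    c(v, rep(0L, width - length(v)))
  })
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(d[i, j], sum(abs(padded[[i]] - padded[[j]])))
    }
  }
})

test_that("length correlation is 1 for collinear data, ~0 for unrelated B, and errors on constant L", {
  prof <- structure(
    data.frame(id = paste0("s", 1:6), L = c(10, 20, 30, 40, 50, 60),
               tandem_factor = 1L, B = 2 * c(10, 20, 30, 40, 50, 60) + 3),
    class = c("compression_profile", "data.frame")
  )
  expect_equal(suppressWarnings(length_correlation(prof)), 1)
  set.seed(14)
  prof$B <- 100 + rnorm(6, sd = 0.01)   # B unrelated to L
  expect_lt(length_correlation(prof), 0.5)
  prof$L <- rep(5, 6)
  expect_error(length_correlation(prof), "constant")
})
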