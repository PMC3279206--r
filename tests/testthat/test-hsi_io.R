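test_that("ENVI cube write/read round-trips bit-for-bit", {
  set.seed(11)
  cube <- spectral_cube(array(rnorm(3 * 4 * 5)^2, c(3, 4, 5)),
                        wavelengths_nm = seq(600, 640, by = 10),
                        kind = "reflectance")
  for (il in c("bsq", "bil", "bip")) {
    hdr <- file.path(withr::local_tempdir(), paste0("c_", il, ".hdr"))
    write_envi_cube(cube, hdr, interleave = il, data_type = 5)  # float64: lossless
    back <- read_envi_cube(hdr)
    expect_identical(back$data, cube$data)
    expect_identical(back$wavelengths_nm, cube$wavelengths_nm)
    expect_identical(back$kind, cube$kind)
  }
  # float32 round trip on exactly representable values
  cube32 <- spectral_cube(array(seq_len(60) / 256, c(3, 4, 5)),
                          seq(600, 640, by = 10), "reflectance")
  hdr <- file.path(withr::local_tempdir(), "f32.hdr")
  write_envi_cube(cube32, hdr, data_type = 4)
  expect_identical(read_envi_cube(hdr)$data, cube32$data)
  # uint16 raw counts
  raw <- spectral_cube(array(sample(0:40000, 24), c(3, 4, 2)),
                       c(600, 700), "raw")
  hdr <- file.path(withr::local_tempdir(), "u16.hdr")
  write_envi_cube(raw, hdr, data_type = 12)
  expect_equal(read_envi_cube(hdr)$data, raw$data)
})

test_that("all three interleaves lay bytes out per index arithmetic and read identically", {
  set.seed(7)
  cube <- spectral_cube(array(rnorm(2 * 3 * 2), c(2, 3, 2)),
                        c(600, 800), "reflectance")
  read_back <- list()
  for (il in c("bsq", "bil", "bip")) {
    hdr <- file.path(withr::local_tempdir(), paste0(il, ".hdr"))
    write_envi_cube(cube, hdr, interleave = il, data_type = 5)
    oracle <- envi_byte_oracle(hdr, 2, 3, 2, il)
    expect_equal(oracle, cube$data, tolerance = 0)
    read_back[[il]] <- read_envi_cube(hdr)$data
  }
  expect_identical(read_back$bsq, read_back$bil)
  expect_identical(read_back$bsq, read_back$bip)
})

test_that("single-pixel cube stores exactly B samples in band order", {
  cube <- spectral_cube(array(c(0.25, 0.5), c(1, 1, 2)), c(600, 700), "reflectance")
  hdr <- file.path(withr::local_tempdir(), "tiny.hdr")
  write_envi_cube(cube, hdr, data_type = 4)
  con <- file(sub("\\.hdr$", ".raw", hdr), "rb")
  v <- readBin(con, "numeric", 3, size = 4, endian = "little")
  close(con)
  expect_equal(v, c(0.25, 0.5))
})

test_that("header/data inconsistencies raise format or consistency errors", {
  cube <- spectral_cube(array(1, c(2, 2, 3)), c(600, 650, 700), "reflectance")
  hdr <- file.path(withr::local_tempdir(), "bad.hdr")
  write_envi_cube(cube, hdr)
  # corrupt the wavelength block to declare 81 bands' worth of wavelengths
  txt <- readLines(hdr)
  txt[grep("^wavelength =", txt)] <-
    sprintf("wavelength = {%s}", paste(seq(600, 1000, 5), collapse = ", "))
  writeLines(txt, hdr)
  expect_error(read_envi_cube(hdr), class = "srhsi_consistency_error")
  writeLines("not a header", hdr)
  expect_error(read_envi_cube(hdr), class = "srhsi_format_error")
  expect_error(read_envi_cube(file.path(tempdir(), "nope.hdr")),
               class = "srhsi_format_error")
})

test_that("mask round trips are lossless for PNG and PGM; RGB input is rejected", {
  set.seed(3)
  m <- label_mask(matrix(sample(c(0L, 1L, 255L), 24, TRUE), 4, 6))
  for (ext in c("png", "pgm")) {
    p <- file.path(withr::local_tempdir(), paste0("m.", ext))
    write_mask(m, p)
    expect_identical(read_mask(p)$labels, m$labels)
  }
  # all-zero image
  p0 <- file.path(withr::local_tempdir(), "z.png")
  write_mask(label_mask(matrix(0L, 4, 4)), p0)
  expect_identical(read_mask(p0)$labels, matrix(0L, 4, 4))
  # 128 maps to cancerous by default
  p128 <- file.path(withr::local_tempdir(), "g.png")
  png::writePNG(matrix(c(0, 128, 255, 0) / 255, 2, 2), p128)
  expect_identical(read_mask(p128)$labels, matrix(c(0L, 1L, 255L, 0L), 2, 2))
  # RGB is not a label mask
  prgb <- file.path(withr::local_tempdir(), "rgb.png")
  png::writePNG(array(runif(12), c(2, 2, 3)), prgb)
  expect_error(read_mask(prgb), class = "srhsi_format_error")
})

test_that("dictionary tables round-trip atoms and class partition", {
  set.seed(5)
  dict <- build_dictionary(matrix(runif(9), 3, 3), matrix(runif(6), 2, 3),
                           wavelengths_nm = c(600, 700, 800))
  p <- file.path(withr::local_tempdir(), "dict.csv")
  save_dictionary(dict, p)
  txt <- readLines(p)
  expect_length(txt, 6L)  # header + 5 atoms
  expect_length(strsplit(txt[2], ",")[[1]], 4L)  # class + B values
  back <- load_dictionary(p)
  expect_equal(back$atoms, dict$atoms, tolerance = 1e-13)
  expect_identical(back$n_noncancerous, dict$n_noncancerous)
  expect_identical(back$n_cancerous, dict$n_cancerous)
  expect_true(back$normalized)
  # short row is a format error
  writeLines(c("class,600,700,800", "noncancerous,0.1,0.2"), p)
  expect_error(load_dictionary(p), class = "srhsi_format_error")
})

test_that("cube constructor enforces its invariants", {
  expect_error(spectral_cube(array(1, c(2, 2, 3)), c(600, 600, 700)),
               class = "srhsi_consistency_error")
  expect_error(spectral_cube(array(-1, c(2, 2, 3)), c(600, 650, 700), "raw"),
               class = "srhsi_consistency_error")
  expect_error(spectral_cube(array(1, c(2, 2, 3)), c(600, 650)),
               class = "srhsi_consistency_error")
  expect_error(label_mask(matrix(c(0L, 7L), 1, 2)), class = "srhsi_format_error")
})
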