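make_image <- function(n = 3, peaks = 5, mode = "processed", seed = 1) {
  set.seed(seed)
  spectra <- lapply(seq_len(n), function(i) {
    if (mode == "continuous") {
      list(mz = seq(600, 900, length.out = peaks),
           intensity = runif(peaks, 0, 100))
    } else {
      list(mz = sort(runif(peaks, 600, 1000)),
           intensity = runif(peaks, 0, 100))
    }
  })
  msi_image("pt_io", data.frame(x = seq_len(n) - 1L, y = 0L), spectra,
            mode = mode, spatial_resolution = 100)
}

roundtrip <- function(img, path, mode = img$mode) {
  write_imzml(img, path, mode = mode)
  read_imzml(path)
}

test_that("processed-mode imzML round-trips spectra, coordinates and metadata", {
  img <- make_image(4, 7)
  got <- roundtrip(img, file.path(tempdir(), "rt.imzML"))
  expect_identical(got$coords, img$coords)
  expect_identical(got$mode, "processed")
  expect_identical(got$patient_id, "pt_io")
  expect_equal(got$spatial_resolution, 100)
  for (i in seq_along(img$spectra)) {
    expect_equal(got$spectra[[i]]$mz, img$spectra[[i]]$mz, tolerance = 0)
    expect_equal(got$spectra[[i]]$intensity, img$spectra[[i]]$intensity,
                 tolerance = 1e-6)
  }
})

test_that("continuous-mode imzML shares one m/z axis and round-trips", {
  img <- make_image(3, 6, mode = "continuous")
  got <- roundtrip(img, file.path(tempdir(), "rtc.imzML"))
  expect_identical(got$mode, "continuous")
  expect_equal(got$spectra[[2]]$mz, img$spectra[[1]]$mz)
  expect_equal(got$spectra[[3]]$intensity, img$spectra[[3]]$intensity,
               tolerance = 1e-6)
})

test_that("continuous mode with ragged axes is a mode error", {
  img <- make_image(3, 5, mode = "processed")
  expect_error(write_imzml(img, file.path(tempdir(), "bad.imzML"),
                           mode = "continuous"), "ragged")
})

test_that("single-pixel and empty images round-trip", {
  one <- msi_image("p1", data.frame(x = 0L, y = 0L),
                   list(list(mz = c(650.1, 700.2), intensity = c(5, 7))))
  got <- roundtrip(one, file.path(tempdir(), "one.imzML"))
  expect_equal(got$spectra[[1]]$mz, c(650.1, 700.2))
  none <- msi_image("p0", data.frame(x = integer(0), y = integer(0)), list())
  got0 <- roundtrip(none, file.path(tempdir(), "none.imzML"))
  expect_length(got0$spectra, 0)
})

test_that("missing binary companion is an I/O error", {
  img <- make_image(2, 4)
  p <- file.path(tempdir(), "orphan.imzML")
  write_imzml(img, p)
  file.remove(sub("\\.imzML$", ".ibd", p))
  expect_error(read_imzml(p), "companion")
})

test_that("non-ascending m/z in the binary data is a format error naming the pixel", {
  img <- make_image(2, 4)
  p <- file.path(tempdir(), "scrambled.imzML")
  write_imzml(img, p)
  ibd <- sub("\\.imzML$", ".ibd", p)
  con <- file(ibd, "r+b")
  seek(con, 16, rw = "write") # first spectrum's m/z array starts after UUID
  writeBin(rev(img$spectra[[1]]$mz), con, size = 8, endian = "little")
  close(con)
  expect_error(read_imzml(p), "ascending")
})

test_that("the written imzML is readable by an independent parser", {
  img <- make_image(3, 5, seed = 4)
  p <- file.path(tempdir(), "xcheck.imzML")
  write_imzml(img, p)
  script <- file.path(tempdir(), "read_imzml.py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, it = p.getspectrum(0)",
    "print(json.dumps({'coords': [list(c) for c in p.coordinates],",
    "                  'mz': list(mz), 'intensity': [float(v) for v in it]}))"
  ), script)
  out <- suppressWarnings(system2("python", c(script, p),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0,
              info = paste(out, collapse = "\n"))
  parsed <- jsonlite::fromJSON(out[length(out)])
  # pyimzml reports 1-based (x, y, z) positions
  expect_equal(parsed$coords[, 1], img$coords$x + 1L)
  expect_equal(parsed$mz, img$spectra[[1]]$mz, tolerance = 1e-12)
  expect_equal(parsed$intensity, img$spectra[[1]]$intensity, tolerance = 1e-6)
})

test_that("mask TSV round-trips, rejects bad labels, and validates against images", {
  m <- roi_mask(data.frame(x = c(0L, 1L), y = c(0L, 0L),
                           label = c("background", "cancer_tissue")))
  p <- file.path(tempdir(), "mask.tsv")
  write_mask(m, p)
  expect_identical(read_mask(p), m)
  writeLines("x\ty\tlabel", p)
  expect_equal(nrow(read_mask(p)), 0)
  expect_error(roi_mask(data.frame(x = 0, y = 0, label = "stroma")), "stroma")
  img <- make_image(2, 3)
  off_grid <- roi_mask(data.frame(x = 9L, y = 9L, label = "benign_tissue"))
  expect_error(validate_mask(img, off_grid), "absent")
})

test_that("metadata TSV round-trips with empty-string missing fields", {
  meta <- data.frame(
    patient_id = c("P001", "P002"), diagnosis = c("cancer", "benign"),
    grade = c("2", NA), stage = c("IA", NA),
    phenotype = c("high_risk", "low_risk"), stringsAsFactors = FALSE
  )
  p <- file.path(tempdir(), "meta.tsv")
  write_metadata(meta, p)
  expect_identical(read_metadata(p), meta)
  bad <- meta; bad$grade[2] <- "1"
  write_metadata(bad, p)
  expect_error(read_metadata(p), "benign")
})

test_that("a serialized cohort reproduces the in-memory peak matrix", {
  cfg <- tiny_config(seed = 31, n_cancer = 2L, n_benign = 2L)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  dir.create(dir, showWarnings = FALSE)
  back <- vector("list", length(co$images))
  for (i in seq_along(co$images)) {
    p <- file.path(dir, paste0(co$meta$patient_id[i], ".imzML"))
    write_imzml(co$images[[i]], p)
    back[[i]] <- read_imzml(p)
  }
  pm_mem <- patient_profiles(co$images, co$masks, co$meta)
  pm_disk <- patient_profiles(back, co$masks, co$meta)
  expect_equal(pm_disk$mz, pm_mem$mz, tolerance = 1e-9)
  expect_equal(pm_disk$intensities, pm_mem$intensities, tolerance = 1e-5)
})
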