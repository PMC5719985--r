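test_that("rendering is deterministic and stores ground truth 1:1", {
  cells <- layoutCells(10, 5, 3, seed = 1)
  img1 <- renderWell(cells, seed = 2)
  img2 <- renderWell(cells, seed = 2)
  expect_identical(img1$dna, img2$dna)
  expect_identical(img1$marker, img2$marker)
  expect_identical(img1$truth, cells)
  img3 <- renderWell(cells, seed = 3)
  expect_false(identical(img1$dna, img3$dna))
})

test_that("an empty layout renders background only and segments to nothing", {
  none <- layoutCells(0, 0, 0, seed = 1)
  img <- renderWell(none, noiseSd = 0.01, seed = 1)
  expect_lt(max(img$dna), 0.1)
  expect_equal(nrow(segmentNuclei(img)), 0)
  # an all-zero image is an empty result, not an error
  blank <- list(dna = matrix(0, 64, 64), marker = matrix(0, 64, 64))
  expect_equal(nrow(segmentNuclei(blank)), 0)
})

test_that("well-separated intact nuclei are all detected", {
  cells <- layoutCells(50, 0, 0, seed = 4)
  seg <- segmentNuclei(renderWell(cells, noiseSd = 0.01, seed = 4))
  expect_equal(nrow(seg), 50)
  expect_true(all(seg$n_fragments == 1))
})

test_that("viability follows fragmentation, solidity and area", {
  # one round nucleus of nominal area
  one <- renderWell(data.frame(x = 40, y = 40, viable = TRUE,
                               marker_positive = FALSE),
                    shape = c(80, 80), seed = 1)
  segOne <- callViability(segmentNuclei(one))
  expect_true(segOne$viable)
  # a fragmented nucleus is non-viable
  dead <- renderWell(data.frame(x = 40, y = 40, viable = FALSE,
                                marker_positive = FALSE),
                     shape = c(80, 80), seed = 6)
  segDead <- callViability(segmentNuclei(dead))
  expect_true(all(!segDead$viable))
  # direct rule checks on constructed feature rows
  rows <- data.frame(label = 1:3, x = 0, y = 0, area = c(100, 100, 20),
                     n_fragments = c(1, 4, 1), solidity = c(0.95, 0.95, 0.95),
                     marker_mean_intensity = 0)
  got <- callViability(rows)
  expect_equal(got$viable, c(TRUE, FALSE, FALSE))
})

test_that("segmentation recall and precision exceed 0.95 at mid noise", {
  prec <- rec <- numeric(10)
  for (s in 1:10) {
    cells <- layoutCells(35, 15, 8, seed = s)
    seg <- callViability(segmentNuclei(renderWell(cells, noiseSd = 0.05,
                                                  seed = s)))
    # match each truth cell to the nearest segmented group within 6 px
    d <- outer(seq_len(nrow(cells)), seq_len(nrow(seg)), function(i, j)
      sqrt((cells$x[i] - seg$x[j])^2 + (cells$y[i] - seg$y[j])^2))
    matched <- apply(d, 1, min) < 6
    rec[s] <- mean(matched)
    prec[s] <- sum(matched) / nrow(seg)
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(prec), 0.95)
})

test_that("image-derived viable counts track ground truth (r >= 0.99)", {
  set.seed(9)
  est <- truth <- numeric(20)
  for (i in 1:20) {
    nv <- sample(15:38, 1); nd <- sample(5:18, 1)
    npos <- round(nv * 0.6)
    cells <- layoutCells(npos, nv - npos, nd, seed = i)
    seg <- callViability(segmentNuclei(renderWell(cells, seed = i + 100)))
    est[i] <- sum(seg$viable); truth[i] <- nv
  }
  expect_gte(cor(est, truth), 0.99)
})

test_that("marker gating splits bimodal wells and ignores unimodal ones", {
  bi <- data.frame(marker_mean_intensity = c(rep(10, 50), rep(200, 30)))
  expect_equal(sum(callMarker(bi)$marker_positive), 30)
  uni <- data.frame(marker_mean_intensity = rnorm(100, 20, 2))
  expect_equal(sum(callMarker(uni)$marker_positive), 0)
  allneg <- layoutCells(0, 40, 5, seed = 3)
  seg <- callMarker(callViability(segmentNuclei(renderWell(allneg, seed = 3))))
  expect_equal(sum(seg$marker_positive), 0)
})

test_that("estimated blast fraction is within 0.05 of truth over 20 wells", {
  err <- numeric(20)
  for (s in 1:20) {
    cells <- layoutCells(30, 20, 10, seed = s)
    seg <- callMarker(callViability(segmentNuclei(renderWell(cells, seed = s))))
    est <- sum(seg$viable & seg$marker_positive) / sum(seg$viable)
    err[s] <- est - 0.6
  }
  expect_lt(max(abs(err)), 0.05)
})

test_that("marker calls can be OR-combined across channels", {
  expect_equal(combineMarkersOr(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE)),
               c(TRUE, FALSE, TRUE))
})

test_that("calls are invariant to a common intensity scaling", {
  cells <- layoutCells(20, 15, 8, seed = 12)
  img <- renderWell(cells, seed = 12)
  big <- img; big$dna <- img$dna * 40; big$marker <- img$marker * 40
  a <- callMarker(callViability(segmentNuclei(img)))
  b <- callMarker(callViability(segmentNuclei(big)))
  expect_equal(a$viable, b$viable)
  expect_equal(a$marker_positive, b$marker_positive)
})

test_that("viable count never exceeds detected groups; positives are a subset", {
  cells <- layoutCells(25, 15, 10, seed = 20)
  seg <- callMarker(callViability(segmentNuclei(renderWell(cells, seed = 20))))
  expect_lte(sum(seg$viable), nrow(seg))
  expect_true(all(which(seg$marker_positive) %in% seq_len(nrow(seg))))
})

test_that("segmented wells convert to well-table records", {
  cells <- data.frame(viable = rep(c(TRUE, TRUE, FALSE), c(30, 50, 20)),
                      marker_positive = rep(c(TRUE, FALSE, FALSE),
                                            c(30, 50, 20)))
  rec <- imageToWellRecord(cells, "P1", "plate1", "A1", "DMSO", 0, 1, "CD34")
  expect_equal(rec$n_viable_marker_pos, 30)
  expect_equal(rec$n_viable_marker_neg, 50)
  expect_equal(rec$n_total_cells, 100)
  emptyRec <- imageToWellRecord(cells[0, ], "P1", "plate1", "A2", "d", 1, 1,
                                "CD34")
  expect_equal(emptyRec$n_viable_marker_pos + emptyRec$n_viable_marker_neg, 0)
})

test_that("the image path reproduces the count-level RBF", {
  # 4 control + 4 treated wells; on-target kill 0.5 on the marker+ cells
  set.seed(33)
  kill <- 0.5
  recs <- list()
  for (w in 1:8) {
    treated <- w > 4
    npos0 <- 24; nneg <- 24
    npos <- if (treated) rbinom(1, npos0, 1 - kill) else npos0
    ndead <- 8 + (npos0 - npos)
    cells <- layoutCells(npos, nneg, ndead, seed = 100 + w)
    seg <- callMarker(callViability(segmentNuclei(renderWell(cells,
                                                             seed = 200 + w))))
    recs[[w]] <- imageToWellRecord(
      seg, "P1", "plate1", paste0("A", w),
      drug = if (treated) "drugZ" else "DMSO",
      concentration = if (treated) 1 else 0,
      replicate = ((w - 1) %% 4) + 1, marker = "CD34")
  }
  tab <- do.call(rbind, recs)
  scr <- WellScreen(tab)
  rImg <- computeRBF(scr, "P1", "CD34", "drugZ")
  # count-level truth from the same generated cell populations
  truthCounts <- do.call(rbind, lapply(1:8, function(w) {
    treated <- w > 4
    data.frame(treated = treated,
               pos = tab$n_viable_marker_pos[w],
               neg = tab$n_viable_marker_neg[w])
  }))
  ctlFrac <- with(truthCounts[!truthCounts$treated, ], mean(pos / (pos + neg)))
  trtRbf <- with(truthCounts[truthCounts$treated, ], (pos / (pos + neg)) / ctlFrac)
  expect_equal(rImg$rbf_mean, mean(trtRbf))
  # and the image-derived mean RBF is near the expected attenuation
  f <- 0.5
  expect_lt(abs(rImg$rbf_mean - expectedRBF(f, kill, 0)), 0.2)
})

test_that("TIFF stacks round-trip both channels up to a common scale", {
  cells <- layoutCells(5, 5, 2, shape = c(96, 96), spacing = 24, seed = 2)
  img <- renderWell(cells, shape = c(96, 96), seed = 2)
  path <- tempfile(fileext = ".tif")
  writeWellTiff(img, path)
  back <- readWellTiff(path)
  expect_equal(dim(back$dna), dim(img$dna))
  sc <- max(img$dna, img$marker)
  expect_lt(max(abs(back$dna * sc - img$dna)), 1e-4)
  expect_lt(max(abs(back$marker * sc - img$marker)), 1e-4)
  # calls on the round-tripped image are unchanged (scale invariance)
  a <- callViability(segmentNuclei(img))
  b <- callViability(segmentNuclei(back))
  expect_equal(a$viable, b$viable)
})
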