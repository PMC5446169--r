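dp33 <- dearray_params(3, 3, invert_labels = FALSE)

test_that("clean 3x3 TMA yields nine blobs near ground-truth centroids", {
  tma <- gen_tma_image(3, 3, spacing = 40, core_radius = 12, seed = 1)
  blobs <- detect_cores(tma$thumb, dp = dp33)
  expect_equal(nrow(blobs), 9)
  truth <- tma$truth
  for (i in seq_len(nrow(blobs))) {
    d <- sqrt(min((truth$cx - blobs$centroid_x[i])^2 +
                    (truth$cy - blobs$centroid_y[i])^2))
    expect_lt(d, 2)
  }
})

test_that("closing merges core fragments within the structuring radius", {
  tma <- gen_tma_image(3, 3, spacing = 50, core_radius = 15,
                       fragment_prob = 1, seed = 3)
  blobs <- detect_cores(tma$thumb, dp = dp33)
  expect_equal(nrow(blobs), 9)  # half-disks 3 px apart stay one object
})

test_that("debris specks are removed by the area filter", {
  tma <- gen_tma_image(3, 3, spacing = 50, core_radius = 15,
                       debris_count = 6, seed = 9)
  blobs <- detect_cores(tma$thumb, dp = dp33)
  expect_equal(nrow(blobs), 9)
})

test_that("an object of merged cores is dropped, other cores unaffected", {
  tma <- gen_tma_image(3, 3, spacing = 50, core_radius = 15, seed = 2)
  thumb <- tma$thumb
  # bridge cores (1,1) and (1,2) with tissue so they merge into one object
  t1 <- tma$truth[tma$truth$row == 1 & tma$truth$col == 1, ]
  t2 <- tma$truth[tma$truth$row == 1 & tma$truth$col == 2, ]
  xs <- round(t1$cx):round(t2$cx)
  ys <- round(t1$cy) + (-3:3)
  npx <- length(xs) * length(ys)
  cols <- ihcquant:::.draw_unstained(npx, pixel_class_params())
  k <- 0
  for (x in xs) for (y in ys) {
    k <- k + 1
    thumb[y, x, ] <- cols[k, ]
  }
  # single cores are ~707 px^2; the bridged pair is well over 1000 px^2
  dp_bounds <- dearray_params(3, 3, min_area = 300, max_area = 1000,
                              invert_labels = FALSE)
  blobs <- detect_cores(thumb, dp = dp_bounds)
  expect_equal(nrow(blobs), 7)  # merged pair removed, 7 cores survive
  # survivors are still within 2 px of their true centroids
  truth <- tma$truth[!(tma$truth$row == 1 & tma$truth$col <= 2), ]
  for (i in seq_len(nrow(blobs))) {
    d <- sqrt(min((truth$cx - blobs$centroid_x[i])^2 +
                    (truth$cy - blobs$centroid_y[i])^2))
    expect_lt(d, 2)
  }
})

test_that("empty slides raise an empty-detection error", {
  tma <- gen_tma_image(3, 3, spacing = 40, core_radius = 12,
                       missing_prob = 1, seed = 1)
  expect_error(detect_cores(tma$thumb, dp = dp33), "no foreground")
})

test_that("origin core has minimal coordinate sum with y-then-x ties", {
  tab <- centroid_table(data.frame(centroid_x = c(10, 10, 50),
                                   centroid_y = c(10, 50, 10)))
  expect_equal(find_origin_core(tab), 1L)
  tie <- centroid_table(data.frame(centroid_x = c(0, 40),
                                   centroid_y = c(40, 0)))
  expect_equal(find_origin_core(tie), 2L)  # smaller y wins the tie
  single <- centroid_table(data.frame(centroid_x = 5, centroid_y = 7))
  expect_equal(find_origin_core(single), 1L)
  expect_error(find_origin_core(single[0, ]), "empty")
})

test_that("a perfect lattice is assigned identically", {
  tab <- lattice_table(3, 3)
  g <- assemble_grid(tab, dp33)
  expect_equal(g$centroids$assigned_row, g$centroids$true_row)
  expect_equal(g$centroids$assigned_col, g$centroids$true_col)
})

test_that("a missing interior cell is bridged by the expanded search", {
  tab <- lattice_table(3, 3, drop = data.frame(row = 2, col = 2))
  g <- assemble_grid(tab, dp33)
  expect_equal(g$centroids$assigned_row, g$centroids$true_row)
  expect_equal(g$centroids$assigned_col, g$centroids$true_col)
  expect_true(is.na(g$matrix[2, 2]))
  expect_equal(sum(!is.na(g$matrix)), 8)
})

test_that("a missing top-left corner does not shift the labels", {
  tab <- lattice_table(4, 4, drop = data.frame(row = c(1, 2), col = c(1, 3)))
  g <- assemble_grid(tab, dearray_params(4, 4, invert_labels = FALSE))
  expect_equal(g$centroids$assigned_row, g$centroids$true_row)
  expect_equal(g$centroids$assigned_col, g$centroids$true_col)
})

test_that("jittered, decimated 5x5 arrays recover all true cells", {
  dp <- dearray_params(5, 5, invert_labels = FALSE)
  for (s in 1:10) {
    tma <- gen_tma_image(5, 5, spacing = 60, core_radius = 18,
                         jitter_fraction = 0.1, missing_prob = 0.2,
                         seed = s)
    blobs <- detect_cores(tma$thumb, dp = dp)
    g <- assemble_grid(centroid_table(blobs), dp)
    tab <- g$centroids
    truth <- tma$truth[tma$truth$present, ]
    expect_equal(nrow(tab), nrow(truth))
    for (i in seq_len(nrow(tab))) {
      j <- which.min((truth$cx - tab$centroid_x[i])^2 +
                       (truth$cy - tab$centroid_y[i])^2)
      expect_equal(tab$assigned_row[i], truth$row[j])
      expect_equal(tab$assigned_col[i], truth$col[j])
    }
  }
})

test_that("no two cores ever share a grid cell", {
  dp <- dearray_params(5, 5, invert_labels = FALSE)
  for (s in 1:5) {
    tma <- gen_tma_image(5, 5, spacing = 60, core_radius = 18,
                         jitter_fraction = 0.08, missing_prob = 0.15,
                         seed = 100 + s)
    g <- assemble_grid(centroid_table(detect_cores(tma$thumb, dp = dp)), dp)
    cells <- with(g$centroids,
                  paste(assigned_row, assigned_col)[!is.na(assigned_row)])
    expect_equal(anyDuplicated(cells), 0L)
  }
})

test_that("label inversion flips first and last and is an involution", {
  tab <- lattice_table(4, 3)
  g <- assemble_grid(tab, dearray_params(4, 3, invert_labels = FALSE))
  gi <- invert_grid_labels(g)
  i_first <- which(g$centroids$true_row == 1 & g$centroids$true_col == 1)
  expect_equal(gi$centroids$assigned_row[i_first], 4L)
  expect_equal(gi$centroids$assigned_col[i_first], 3L)
  gii <- invert_grid_labels(gi)
  expect_equal(gii$centroids$assigned_row, g$centroids$assigned_row)
  expect_equal(gii$centroids$assigned_col, g$centroids$assigned_col)
  g1 <- assemble_grid(lattice_table(1, 1), dearray_params(1, 1))
  expect_equal(invert_grid_labels(g1)$centroids$assigned_row, 1L)
})

test_that("centroid scaling multiplies per axis and rounds half-even", {
  tab <- data.frame(centroid_x = 100, centroid_y = 200)
  s <- scale_centroids(tab, c(800, 1000), c(3200, 4000))
  expect_equal(s$centroid_full_x, 400)
  expect_equal(s$centroid_full_y, 800)
  same <- scale_centroids(tab, c(800, 1000), c(800, 1000))
  expect_equal(same$centroid_full_x, 100)
  halves <- data.frame(centroid_x = 33, centroid_y = 17)
  s2 <- scale_centroids(halves, c(100, 100), c(250, 250))
  expect_equal(s2$centroid_full_x, 82)  # 82.5 rounds half-even to 82
  expect_equal(s2$centroid_full_y, 42)  # 42.5 rounds half-even to 42
  expect_error(scale_centroids(tab, c(100, 100), c(200, 300)),
               "aspect-ratio")
})

test_that("score_core recovers a core's known stain fraction", {
  tma <- gen_tma_image(3, 3, spacing = 50, core_radius = 15,
                       core_stain_fraction = 0.3, seed = 6)
  t22 <- tma$truth[tma$truth$row == 2 & tma$truth$col == 2, ]
  q <- score_core(tma$full, t22$cx_full, t22$cy_full,
                  window_side = 50 * tma$scale)
  expect_equal(q$stain_fraction, t22$stain_fraction)
})

test_that("clipped edge windows still conserve pixel tallies", {
  fx <- gen_tissue_image(60, 60, 0.4, 0.5, seed = 8)
  q <- score_core(fx$img, cx = 3, cy = 3, window_side = 31)
  expect_equal(q$total_pixels,
               q$background_pixels + q$stained_pixels + q$unstained_pixels)
  expect_lt(q$total_pixels, 31 * 31)  # window was clipped at the corner
})

test_that("an all-background window warns and reports undefined fraction", {
  bg <- gen_tissue_image(40, 40, 0, 0, seed = 9)
  expect_warning(q <- score_core(bg$img, 20, 20, 15), "no sample")
  expect_equal(q$sample_pixels, 0)
  expect_true(is.na(q$stain_fraction))
})

test_that("annotations join on (row, col) with loud mismatch handling", {
  rec <- data.frame(row = c(1, 2), col = c(1, 3),
                    stain_fraction = c(0.2, 0.4))
  ann <- data.frame(row = 2, col = 3, gleason = 7)
  expect_warning(out <- join_annotations(rec, ann), "no annotation")
  expect_equal(out$gleason, c(NA, 7))
  expect_message(
    suppressWarnings(join_annotations(rec,
                                      rbind(ann, data.frame(row = 9, col = 9,
                                                            gleason = 6)))),
    "9:9")
  expect_error(join_annotations(rec, rbind(ann, ann)), "duplicate")
})

test_that("exported results round-trip and keep undefined fractions empty", {
  rec <- data.frame(centroid_x = c(10, 20, 30), centroid_y = c(10, 10, 20),
                    row = c(1, 1, 2), col = c(1, 2, 1),
                    gleason = c(6, 7, NA),
                    stain_fraction = c(0.25, NA, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  export_results(rec, path)
  txt <- readLines(path)
  expect_equal(length(txt), 4)  # header + 3 cores
  back <- read.csv(path)
  expect_equal(back$percent_stained, c(25, NA, 50))
  expect_true(is.na(back$gleason[3]))
})

test_that("the full pipeline scores and annotates a synthetic TMA", {
  tma <- gen_tma_image(3, 3, spacing = 50, core_radius = 15,
                       core_stain_fraction = 0.4, seed = 12)
  ann <- expand.grid(row = 1:3, col = 1:3)
  ann$gleason <- rep(c(6, 7, 8), 3)
  rec <- dearray_tma(tma$thumb, tma$full,
                     dearray_params(3, 3, invert_labels = FALSE),
                     annotations = ann)
  expect_equal(nrow(rec), 9)
  expect_equal(rec$row, rep(1:3, each = 3))
  realized <- tma$truth$stain_fraction[1]
  expect_true(all(abs(rec$stain_fraction - realized) < 1e-12))
  expect_equal(rec$gleason, ann$gleason[order(ann$row, ann$col)])
})

test_that("label inversion in the pipeline reverses the annotation join", {
  tma <- gen_tma_image(2, 2, spacing = 50, core_radius = 15, seed = 13)
  ann <- expand.grid(row = 1:2, col = 1:2)
  ann$gleason <- c(6, 7, 8, 9)
  rec <- dearray_tma(tma$thumb, tma$full,
                     dearray_params(2, 2, invert_labels = TRUE),
                     annotations = ann)
  # the physically top-left core is labeled (2,2) after inversion
  top_left <- which.min(rec$centroid_x + rec$centroid_y)
  expect_equal(rec$row[top_left], 2)
  expect_equal(rec$col[top_left], 2)
})
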