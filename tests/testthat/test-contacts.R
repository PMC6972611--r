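# Minimum proton-proton distances from explicit coordinates, checked against
# a naive all-pairs double loop.

brute_force_min <- function(df, pair) {
  intra <- Inf; inter <- Inf
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (i == j) next
    if (df$group[i] != pair[1] || df$group[j] != pair[2]) next
    d <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
                (df$z[i] - df$z[j])^2)
    if (df$mol_id[i] == df$mol_id[j]) intra <- min(intra, d)
    else inter <- min(inter, d)
  }
  c(intra = intra, inter = inter)
}

random_cloud <- function(n_mol, protons_per_mol = 4) {
  centers <- matrix(runif(3 * n_mol, 0, 30), ncol = 3)
  rows <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    off <- matrix(rnorm(3 * protons_per_mol, 0, 1.5), ncol = 3)
    data.frame(x = centers[m, 1] + off[, 1], y = centers[m, 2] + off[, 2],
               z = centers[m, 3] + off[, 3], mol_id = as.character(m),
               group = sample(c("a", "b", "c"), protons_per_mol,
                              replace = TRUE))
  }))
  proton_cloud(rows)
}

test_that("two single-proton molecules give the expected intermolecular gap", {
  cl <- proton_cloud(data.frame(x = c(0, 2), y = 0, z = 0,
                                mol_id = c("1", "2"), group = c("a", "a")))
  m <- min_group_distances(cl, c("a", "a"))
  expect_equal(m$inter_min_A, 2)
  expect_true(is.na(m$intra_min_A))  # single proton per molecule
})

test_that("a single molecule has no intermolecular distance", {
  cl <- proton_cloud(data.frame(x = c(0, 0), y = c(0, 3), z = 0,
                                mol_id = "1", group = c("a", "b")))
  m <- min_group_distances(cl, c("a", "b"))
  expect_equal(m$intra_min_A, 3)
  expect_false(m$inter_defined)
  expect_true(is.na(m$inter_min_A))
  expect_error(min_group_distances(cl, c("a", "z")), "absent")
})

test_that("vectorized scan matches the all-pairs double loop", {
  set.seed(21)
  cl <- random_cloud(50)
  for (pair in list(c("a", "b"), c("b", "c"), c("a", "a"))) {
    bf <- brute_force_min(as.data.frame(cl), pair)
    m <- min_group_distances(cl, pair)
    expect_equal(m$intra_min_A, unname(bf["intra"]))
    expect_equal(m$inter_min_A, unname(bf["inter"]))
  }
})

test_that("distances are invariant under rigid translation and rotation", {
  set.seed(4)
  cl <- random_cloud(10)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(as.data.frame(cl)[, c("x", "y", "z")]) %*% t(R)
  moved <- cl
  moved$x <- xyz[, 1] + 5; moved$y <- xyz[, 2] - 3; moved$z <- xyz[, 3] + 11
  m1 <- min_group_distances(cl, c("a", "b"))
  m2 <- min_group_distances(moved, c("a", "b"))
  expect_equal(m1$intra_min_A, m2$intra_min_A)
  expect_equal(m1$inter_min_A, m2$inter_min_A)
})

test_that("extended XYZ files roundtrip through read and write", {
  set.seed(5)
  cl <- random_cloud(3)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_groups(cl, path)
  back <- read_xyz_groups(path)
  expect_equal(back$x, cl$x, tolerance = 1e-6)
  expect_equal(back$mol_id, cl$mol_id)
  expect_equal(back$group, cl$group)
})

test_that("crystal reference constants join against NOE distance tables", {
  ref <- crystal_reference_distances()
  expect_true(all(ref$inter_A < ref$intra_A))  # packing brings groups closer
  noe <- data.frame(pair = c("a*-b*", "b*-c*"),
                    distance_angstrom = c(2.04, 2.71),
                    flag_gt_5A = FALSE)
  cmp <- compare_noe_to_crystal(noe)
  expect_equal(nrow(cmp), 4)  # two pairs x two crystal structures
  expect_true(all(abs(cmp$difference_A) ==
                    abs(cmp$noe_distance_A - cmp$inter_A)))
})
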