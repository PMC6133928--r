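test_that("xyz round-trip is identity within write precision", {
  traj <- make_tiny_traj()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  back <- read_xyz(path)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
  expect_equal(back$box, traj$box)
  expect_equal(back$labels, traj$labels)
  expect_equal(back$dt, 0.5)

  gz <- withr::local_tempfile(fileext = ".xyz.gz")
  write_xyz(traj, gz)
  expect_equal(read_xyz(gz)$coords, traj$coords, tolerance = 1e-9)
})

test_that("xyz reader rejects malformed input with located errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "box= 4 4 4", "A 0 0 0", "B 1 1 1", "C 2 2 2",
               "2", "box= 4 4 4", "A 0 0 0", "B 1 1 1"), path)
  expect_error(read_xyz(path), "3 atoms but first frame had|frame has 2")

  writeLines(c("x", "box= 4 4 4", "A 0 0 0"), path)
  expect_error(read_xyz(path), "malformed atom count")

  writeLines(c("1", "no box here", "A 0 0 0"), path)
  expect_error(read_xyz(path), "extended-XYZ")
})

test_that("synthetic ideal-gas file survives an xyz round trip", {
  gas <- gen_ideal_gas(shell_fluid_spec(30, c(3, 3, 3), 4, seed = 11))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(gas, path)
  expect_lt(max(abs(read_xyz(path)$coords - gas$coords)), 1e-6)
})

test_that("gro round-trip holds at format precision and errors are clear", {
  traj <- make_tiny_traj()
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(traj, path)
  back <- read_gro(path)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3 + 1e-12)
  expect_equal(back$box, traj$box, tolerance = 1e-9)
  expect_equal(back$labels, traj$labels)

  # truncated: drop the box line of the last frame
  lines <- readLines(path)
  writeLines(lines[-length(lines)], path)
  expect_error(read_gro(path), "frame 2")

  # triclinic box line rejected
  writeLines(c("t= 0", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MOL", "A", 1L, 1, 1, 1),
               "   4.0   4.0   4.0   0.0   0.0   1.0   0.0   0.0   0.0"), path)
  expect_error(read_gro(path), "triclinic")
})

test_that("xvg parsing skips headers, keeps columns, and names bad rows", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@ title \"pull\"", "0 1.0", "1 2.0", "2 3.0"), path)
  ts <- read_xvg_series(path)
  expect_equal(ts$times, c(0, 1, 2))
  expect_equal(unname(ts$values[, 1]), c(1, 2, 3))

  writeLines(c("0 1.0", "1 oops"), path)
  expect_error(read_xvg_series(path), "line 2")
})

test_that("an umbrella-pull record survives the xvg round trip", {
  ts <- gen_umbrella_pull(umbrella_pull_spec(pmf_zero(), 100, 1e-3, 0.5,
                                             10, 296, 0.01, 200, seed = 4))
  path <- withr::local_tempfile(fileext = ".xvg")
  write_xvg_series(ts, path)
  back <- read_xvg_series(path, col_names = colnames(ts$values))
  expect_equal(back$times, ts$times, tolerance = 1e-9)
  expect_equal(back$values, ts$values, tolerance = 1e-9)
})

test_that("minimum-image distance handles wrapping and matches the 27-image oracle", {
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(0.1, 0, 0)
  coords[2, , 1] <- c(3.9, 0, 0)
  fr <- get_frame(trajectory(coords, c(4, 4, 4)), 1)
  expect_equal(minimum_image_distance(fr, 1, 2), 0.2, tolerance = 1e-12)
  expect_error(minimum_image_distance(fr, 1, 1), "differ")

  # identical up to a full box vector
  coords[2, , 1] <- c(0.1, 4, -8)
  fr <- get_frame(trajectory(coords, c(4, 4, 4)), 1)
  expect_equal(minimum_image_distance(fr, 1, 2), 0, tolerance = 1e-12)

  set.seed(42)
  box <- c(3, 4, 5)
  for (i in 1:50) {
    # inside the box: the 27-image enumeration is then exhaustive
    p <- matrix(runif(6), 2, 3) %*% diag(box)
    coords <- array(t(p)[c(1, 4, 2, 5, 3, 6)], dim = c(2, 3, 1))
    coords[1, , 1] <- p[1, ]; coords[2, , 1] <- p[2, ]
    fr <- get_frame(trajectory(coords, box), 1)
    d <- minimum_image_distance(fr, 1, 2)
    expect_equal(d, brute_min_image(p[1, ], p[2, ], box), tolerance = 1e-12)
    expect_equal(d, minimum_image_distance(fr, 2, 1), tolerance = 1e-15)
    # translation of one atom by an integer box vector changes nothing
    shift <- sample(-2:2, 3, replace = TRUE) * box
    coords[2, , 1] <- p[2, ] + shift
    fr2 <- get_frame(trajectory(coords, box), 1)
    expect_equal(minimum_image_distance(fr2, 1, 2), d, tolerance = 1e-12)
  }
})

test_that("site selection resolves patterns and validates indices", {
  traj <- make_tiny_traj()  # labels OW HW LI
  expect_equal(select_sites(traj, "LI")$indices, 3L)
  expect_equal(select_sites(traj, c(1, 3))$indices, c(1L, 3L))
  expect_error(select_sites(traj, c(1, 1)), "duplicate")
  expect_error(select_sites(traj, "NA+"), "matches no atoms")
  expect_error(select_sites(traj, 7), "outside")
})

test_that("trajectory construction enforces its invariants", {
  coords <- array(runif(12), dim = c(2, 3, 2))
  expect_error(trajectory(coords, c(4, 4, 4), times = c(0, 0.1, 0.3)),
               "length")
  expect_error(trajectory(array(runif(18), dim = c(2, 3, 3)), c(4, 4, 4),
                          times = c(0, 0.1, 0.3)), "uniformly spaced")
  expect_error(trajectory(coords, rep(1, 9)), "triclinic")
  expect_error(trajectory(coords, c(-1, 4, 4)), "> 0")
  coords[1] <- NA
  expect_error(trajectory(coords, c(4, 4, 4)), "finite")
})
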