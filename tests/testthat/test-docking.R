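# Docking orchestration, mock backend, Vina adapter plumbing.

test_that("mock docking is deterministic and respects pose-count limits", {
  tgt <- make_mini_target_fixture()
  p <- docking_params(seed = 3L)
  r1 <- dock(tgt, "CC(=O)Oc1ccccc1C(=O)O", p)
  r2 <- dock(tgt, "CC(=O)Oc1ccccc1C(=O)O", p)
  s1 <- vapply(r1$poses, `[[`, numeric(1), "score")
  s2 <- vapply(r2$poses, `[[`, numeric(1), "score")
  expect_identical(s1, s2)
  expect_lte(length(r1$poses), 9L)
  expect_gte(length(r1$poses), 1L)
  # scores non-decreasing through the pose list
  expect_true(all(diff(s1) >= 0))
})

test_that("preparation rejections block the backend call", {
  tgt <- make_mini_target_fixture()
  expect_error(dock(tgt, "CC.Cl"), "MULTI_FRAGMENT")
  expect_error(dock(tgt, "[CH3]"), "RADICAL")
})

test_that("best_score returns the minimum and flags positive scores", {
  r <- docking_result(list(list(score = -8.5), list(score = -9.1),
                           list(score = -7.0)), "T", "CCO")
  expect_identical(best_score(r), -9.1)

  r1 <- docking_result(list(list(score = -6.2)), "T", "CCO")
  expect_identical(best_score(r1), -6.2)

  rp <- docking_result(list(list(score = 1.3)), "T", "CCO")
  expect_message(v <- best_score(rp), "constrained")
  expect_identical(v, 1.3)
})

test_that("mock scores are pure in the descriptors and bounded", {
  d <- mock_descriptors("CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  w <- mock_target_weights("KIT")
  expect_identical(mock_score(d, w), mock_score(d, w))
  expect_error(mock_score(d[1:3], w), "mismatch")

  # identical weights give identical score columns (rho = 1)
  lib <- fixture_library(25L)
  s1 <- vapply(lib, function(s) mock_score(mock_descriptors(s), w), numeric(1))
  s2 <- vapply(lib, function(s) mock_score(mock_descriptors(s), w), numeric(1))
  expect_identical(s1, s2)
  expect_true(all(s1 > -13 & s1 < -4))
})

test_that("weight construction controls inter-target score correlation", {
  lib <- fixture_library(2000L, seed = 23L)
  sm <- generate_mock_targets(
    list(mock_target_spec("JAK2"),
         mock_target_spec("LCK", correlation_to = "JAK2", rho = 0.8)),
    lib, seed = 5L)
  rho <- cor(sm$scores[, "JAK2"], sm$scores[, "LCK"])
  expect_gt(rho, 0.7)
  expect_lt(rho, 0.9)
  expect_true(all(sm$scores > -13 & sm$scores < -4))

  # rho = 1 means identical columns up to numerical noise
  sm1 <- generate_mock_targets(
    list(mock_target_spec("A"), mock_target_spec("B", correlation_to = "A",
                                                 rho = 1)),
    fixture_library(100L), seed = 6L)
  expect_gt(cor(sm1$scores[, "A"], sm1$scores[, "B"]), 0.999)

  expect_error(mock_target_spec("C", correlation_to = "A", rho = 1.2),
               "infeasible")
})

test_that("vina adapter builds a faithful command line and parses output", {
  tgt <- make_mini_target_fixture()
  args <- dockbench:::vina_command_args(tgt, "rec.pdbqt", "lig.pdbqt",
                                        "out.pdbqt", docking_params(seed = 42L))
  expect_identical(args[which(args == "--seed") + 1L], "42")
  expect_identical(args[which(args == "--exhaustiveness") + 1L], "8")
  expect_identical(args[which(args == "--num_modes") + 1L], "9")
  expect_identical(args[which(args == "--energy_range") + 1L], "3")
  expect_identical(as.numeric(args[which(args == "--center_x") + 1L]),
                   tgt$box$center[["x"]])

  # parse a representative (synthetic) Vina result table
  stdout_text <- paste(c(
    "AutoDock Vina v1.2.3 (synthetic transcript for parser tests)",
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    "   1       -9.123          0          0",
    "   2       -8.744      1.512      2.341",
    "   3       -7.001      2.101      3.871"
  ), collapse = "\n")
  scores <- dockbench:::parse_vina_scores(stdout_text)
  expect_identical(scores, c(-9.123, -8.744, -7.001))
  expect_match(dockbench:::vina_version_string(stdout_text), "AutoDock Vina")

  pose_lines <- c(
    "MODEL 1",
    "ATOM      1  C   UNL     1       1.000   2.000   3.000  0.00  0.00    +0.010 C ",
    "ENDMDL",
    "MODEL 2",
    "ATOM      1  C   UNL     1       1.500   2.500   3.500  0.00  0.00    +0.010 C ",
    "ENDMDL")
  poses <- dockbench:::parse_vina_poses(pose_lines)
  expect_length(poses, 2L)
  expect_equal(poses[[1]][1, ], c(x = 1, y = 2, z = 3))
})

test_that("pose files are MODEL-separated, one per pose", {
  tgt <- make_mini_target_fixture()
  r <- dock(tgt, "CCO", docking_params(seed = 1L))
  dir <- withr::local_tempdir()
  paths <- write_poses(r, dir)
  expect_length(paths, length(r$poses))
  first <- readLines(paths[[1]])
  expect_match(first[[1]], "^MODEL 1")
  expect_identical(first[[length(first)]], "ENDMDL")
})
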