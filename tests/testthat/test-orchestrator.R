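test_that("share_constants reduces to the maximum and rejects bad input", {
  expect_equal(share_constants(3), 3)
  expect_equal(share_constants(c(1, 5, 2)), 5)
  expect_error(share_constants(c(1, NA)), "finite")
  expect_error(share_constants(numeric(0)), "finite")
})

test_that("channels round-trip payloads with last-writer-wins semantics", {
  plan <- partition_cardiac(6, 2, capacities = c(1, 1))  # split 3 + 3
  ch <- dependency_channels(plan)
  fr1 <- array(1 + 2i, c(2, 2, 1, 2))
  publish_dependencies(ch, 1, list(`3` = fr1), stage = 1, iteration = 4)
  got <- retrieve_dependencies(ch, 2)
  expect_identical(got$left$payload, fr1)
  expect_identical(got$left$stage, 1L)
  expect_identical(got$left$iter, 4L)
  expect_false(got$left$final)
  expect_null(got$right)            # device 2 has no right-hand producer
  # nothing published for the other direction yet
  expect_null(retrieve_dependencies(ch, 1)$right$payload)
  # second publish replaces the payload atomically
  fr2 <- array(9 + 0i, c(2, 2, 1, 2))
  publish_dependencies(ch, 1, list(`3` = fr2), stage = 1, iteration = 5,
                       final = TRUE)
  got2 <- retrieve_dependencies(ch, 2)
  expect_identical(got2$left$payload, fr2)
  expect_identical(got2$left$iter, 5L)
  expect_true(got2$left$final)
  # repeated retrieval without a new publish returns the same (final) payload
  got3 <- retrieve_dependencies(ch, 2)
  expect_identical(got3$left$payload, fr2)
  expect_true(got3$left$final)
  # a device must provide the phases its consumers depend on
  expect_error(publish_dependencies(ch, 2, list(), 1, 1),
               "must publish cardiac phase")
})

test_that("a single-device partitioned run equals the plain solver bit for bit", {
  pr <- phantom_problem()
  cfg1 <- recon_config(n_stages = 2, max_iter_per_stage = 10, tol = 1e-4)
  ref <- run_reconstruction(pr$y, pr$coils, cfg1)
  par1 <- run_partitioned(pr$y, pr$coils,
                          recon_config(n_stages = 2, max_iter_per_stage = 10,
                                       tol = 1e-4, n_devices = 1,
                                       exec_mode = "lockstep"))
  expect_identical(par1$image$data, ref$image$data)
  expect_identical(par1$mu0, ref$mu0)
  expect_identical(par1$lambda_reg, ref$lambda_reg)
  expect_identical(par1$device_histories[[1]], ref$histories)
})

test_that("shared constants equal the unpartitioned data-scaled constants", {
  pr <- phantom_problem(Nc = 8)
  cfg <- recon_config(n_stages = 1, max_iter_per_stage = 7, tau = 7,
                      local_stopping = FALSE, n_devices = 3,
                      exec_mode = "lockstep")
  par <- run_partitioned(pr$y, pr$coils, cfg)
  m0 <- apply_encoding_adjoint(pr$y, pr$coils)
  p <- ttv_forward(m0)
  expect_equal(par$mu0, 0.9 * max(Mod(p$cardiac), Mod(p$respiratory)))
  expect_equal(par$lambda_reg, 0.01 * max(Mod(m0$data)))
})

test_that("lockstep consumers always see the current (stage, iteration) stamp", {
  pr <- phantom_problem(Nc = 9)
  cfg <- recon_config(n_stages = 2, max_iter_per_stage = 8, tau = 7,
                      local_stopping = FALSE, n_devices = 3,
                      exec_mode = "lockstep")
  par <- run_partitioned(pr$y, pr$coils, cfg)
  tr <- par$trace
  ret <- tr[tr$event == "retrieve" & tr$stage > 0, ]
  expect_gt(nrow(ret), 0)
  expect_true(all(ret$payload_stage == ret$stage))
  expect_true(all(ret$payload_iter == ret$iteration))
  # stage barriers appear once per stage, after that stage's events
  barriers <- which(tr$event == "barrier")
  expect_identical(length(barriers), 2L)
  expect_true(all(tr$stage[seq_len(barriers[1])] <= 1))
  # no payload ever crosses a stage boundary
  expect_true(all(ret$payload_stage == ret$stage))
})

test_that("every device converges, publishes a final update, then goes idle", {
  pr <- phantom_problem(Nc = 9, af = 2)
  cfg <- recon_config(n_stages = 2, max_iter_per_stage = 50, tau = 7,
                      tol = 1e-3, n_devices = 3, exec_mode = "lockstep")
  par <- run_partitioned(pr$y, pr$coils, cfg)
  tr <- par$trace
  for (q in 1:3) for (s in 1:2) {
    conv <- tr[tr$event == "converged" & tr$device == q & tr$stage == s, ]
    expect_identical(nrow(conv), 1L)
    fin <- tr[tr$event == "final_publish" & tr$device == q & tr$stage == s, ]
    expect_identical(nrow(fin), 1L)
    # the final publish carries the converged iteration's stamp
    expect_identical(fin$iteration, conv$iteration)
    # and no later publish by this device within the stage
    pubs <- tr[tr$event %in% c("publish", "final_publish") &
                 tr$device == q & tr$stage == s, ]
    expect_lte(max(pubs$iteration), conv$iteration)
  }
  # per-device iteration counts are reported per stage
  expect_identical(lengths(par$device_iterations), rep(2L, 3))
  expect_match(format_iterations(par$device_iterations[[1]]),
               "^\\d+ \\+ \\d+ = \\d+$")
})

test_that("lockstep runs are deterministic and concurrent runs seed-reproducible", {
  pr <- phantom_problem(Nc = 8)
  cfgL <- recon_config(n_stages = 2, max_iter_per_stage = 9, tau = 7,
                       local_stopping = FALSE, n_devices = 2,
                       exec_mode = "lockstep")
  a <- run_partitioned(pr$y, pr$coils, cfgL)
  b <- run_partitioned(pr$y, pr$coils, cfgL)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$trace, b$trace)
  cfgC <- recon_config(n_stages = 2, max_iter_per_stage = 9, tau = 7,
                       local_stopping = FALSE, n_devices = 2,
                       exec_mode = "concurrent", seed = 33)
  c1 <- run_partitioned(pr$y, pr$coils, cfgC)
  c2 <- run_partitioned(pr$y, pr$coils, cfgC)
  expect_identical(c1$image$data, c2$image$data)
  expect_identical(c1$trace, c2$trace)
  # with stopping disabled, concurrent interleaving cannot change counts
  expect_identical(c1$device_iterations, a$device_iterations)
})

test_that("concurrent mode leaves the caller's RNG stream untouched", {
  pr <- phantom_problem(Nc = 8)
  cfgC <- recon_config(n_stages = 1, max_iter_per_stage = 7, tau = 7,
                       local_stopping = FALSE, n_devices = 2,
                       exec_mode = "concurrent", seed = 5)
  set.seed(77)
  before <- runif(3)
  set.seed(77)
  invisible(run_partitioned(pr$y, pr$coils, cfgC))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("device count must not exceed the cardiac phase count", {
  pr <- phantom_problem(Nc = 3)
  expect_error(run_partitioned(pr$y, pr$coils,
                               recon_config(n_devices = 4,
                                            exec_mode = "lockstep")),
               "must not exceed Nc")
})

test_that("trace logs serialize as JSON lines", {
  pr <- phantom_problem(Nc = 6)
  par <- run_partitioned(pr$y, pr$coils,
                         recon_config(n_stages = 1, max_iter_per_stage = 7,
                                      tau = 7, local_stopping = FALSE,
                                      n_devices = 2, exec_mode = "lockstep"))
  path <- tempfile(fileext = ".jsonl")
  write_trace_jsonl(par$trace, path)
  lines <- readLines(path)
  expect_identical(length(lines), nrow(par$trace))
  first <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("device", "stage", "iteration", "event") %in%
                    names(first)))
  file.remove(path)
})
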