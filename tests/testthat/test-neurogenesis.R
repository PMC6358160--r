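test_that("newborn GCs get exactly the prescribed random synapse counts", {
  p <- bulb_params(N_GC_aim = 100)
  net <- new_network(p)
  expect_identical(add_gcs(net, p, n = 0), net)
  set.seed(7)
  net2 <- add_gcs(net, p)
  expect_equal(n_gcs(net2), p$N_new_G)
  expect_true(all(colSums(net2$W_MG) == p$N_conn_MG))
  expect_true(all(rowSums(net2$W_GC) == p$N_conn_GC))
  expect_length(validate_network(net2, p), 0)
  # existing wiring untouched
  net3 <- add_gcs(net2, p)
  expect_equal(net3$W_MG[, seq_len(n_gcs(net2))], net2$W_MG)
})

test_that("MC partners of newborn GCs are uniform over the MC population", {
  p <- bulb_params(N_MC = 20, N_CC_odor = 20, N_CC_context = 4,
                   n_contexts = 2, N_conn_MG = 4, N_conn_GC = 2,
                   N_GC_aim = 100)
  set.seed(8)
  net <- add_gcs(new_network(p), p, n = 2500)   # 10^4 synapses
  counts <- rowSums(net$W_MG)
  expect_equal(sum(counts), 2500 * 4)
  # chi-square goodness of fit against the uniform expectation
  pval <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(pval, 0.01)
})

test_that("resilience is the summed suprathreshold response", {
  expect_equal(compute_resilience(matrix(c(1, 2, 3), 1), G_th = 3), 0)
  expect_equal(compute_resilience(matrix(4, 1, 1), G_th = 3), 1)
  expect_equal(compute_resilience(matrix(c(3.5, 2.0, 4.0), 1), G_th = 3), 1.5)
  # vectorized over GCs
  G <- rbind(c(3.5, 2.0, 4.0), c(0, 0, 0))
  expect_equal(compute_resilience(G, 3), c(1.5, 0))
})

test_that("survival probability follows the resilience sigmoid", {
  p <- bulb_params()
  expect_equal(survival_probability(p$R_0, p), 0.5)
  expect_equal(survival_probability(1e3, p), 1)
  expect_equal(survival_probability(3.2, p), (tanh(1) + 1) / 2,
               tolerance = 1e-12)
  expect_equal(survival_probability(3.2, p), 0.8807971, tolerance = 1e-6)
  P <- survival_probability(seq(0, 10, 0.1), p)
  expect_true(all(P > 0 & P <= 1))
  expect_true(all(diff(P) >= 0))
})

test_that("removal is Bernoulli per GC and respects the blockade flag", {
  p <- bulb_params(N_MC = 20, N_CC_odor = 20, N_CC_context = 0,
                   n_contexts = 0, N_conn_MG = 4, N_conn_GC = 2,
                   N_GC_aim = 100)
  set.seed(9)
  net <- add_gcs(new_network(p), p, n = 100)
  keep_all <- remove_gcs(net, rep(1, 100))
  expect_equal(n_gcs(keep_all$net), 100)
  expect_length(keep_all$removed, 0)
  kill_all <- remove_gcs(net, rep(0, 100))
  expect_equal(n_gcs(kill_all$net), 0)
  expect_length(kill_all$removed, 100)
  blocked <- remove_gcs(net, rep(0, 100), apoptosis_blocked = TRUE)
  expect_equal(n_gcs(blocked$net), 100)

  # binomial count at P = 0.5 over many GCs
  set.seed(10)
  big <- add_gcs(new_network(p), p, n = 10000)
  out <- remove_gcs(big, rep(0.5, 10000))
  expect_lt(abs(length(out$removed) - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(remove_gcs(net, rep(0.5, 3)), "one entry per GC")
})

test_that("the inhibition controller pushes g in the homeostatic direction", {
  p <- bulb_params(N_GC_aim = 100)
  expect_equal(adapt_inhibition(1, 100, p), 1)                # in band
  expect_equal(adapt_inhibition(1, 103, p), 1)                # still in band
  expect_gt(adapt_inhibition(1, 200, p), 1)                   # too many GCs
  expect_lt(adapt_inhibition(1, 50, p), 1)                    # too few
  expect_equal(adapt_inhibition(1, 200, p, freeze = TRUE), 1) # frozen
  expect_error(adapt_inhibition(0, 100, p), "positive")
})

test_that("a fully blocked neurogenic step changes nothing but the record", {
  p <- bulb_params(N_MC = 30, N_CC_odor = 30, N_CC_context = 0,
                   n_contexts = 0, N_conn_MG = 4, N_conn_GC = 2,
                   N_GC_aim = 30)
  set.seed(12)
  net <- random_network(p, 10, g = 0.5)
  S <- gaussian_stimulus(data.frame(A = 1.8, x = 15, w = 5), 30)
  env <- environment_of(list(stimulus(S, params = p)))
  out <- neurogenesis_step(net, env, p,
                           flags = list(block_addition = TRUE,
                                        block_removal = TRUE,
                                        freeze_g = TRUE))
  expect_equal(out$net$W_MG, net$W_MG)
  expect_equal(out$net$W_GC, net$W_GC)
  expect_equal(out$net$g, net$g)
  expect_equal(out$record$N_G, 10)
  expect_equal(out$record$n_added, 0)
  expect_equal(out$record$n_removed, 0)
  expect_error(neurogenesis_step(net, env, p, flags = list(bogus = 1)),
               "unknown flag")
})

test_that("evolution is reproducible, grows towards the target band and keeps
           the structural invariants", {
  p <- bulb_params(N_MC = 40, N_CC_odor = 40, N_CC_context = 0,
                   n_contexts = 0, N_conn_MG = 6, N_conn_GC = 2,
                   N_GC_aim = 60, g_init = 0.05, g_gain = 0.03)
  S1 <- gaussian_stimulus(data.frame(A = 1.8, x = 12, w = 5), 40)
  S2 <- gaussian_stimulus(data.frame(A = 1.8, x = 28, w = 5), 40)
  env <- environment_of(list(stimulus(S1, params = p),
                             stimulus(S2, params = p)))
  net <- new_network(p)

  set.seed(33)
  a <- evolve(net, env, p, n_steps = 40)
  set.seed(33)
  b <- evolve(net, env, p, n_steps = 40)
  expect_identical(a$record, b$record)          # bit-identical given the seed
  expect_identical(a$net$W_MG, b$net$W_MG)

  expect_equal(nrow(a$record), 40)
  expect_length(validate_network(a$net, p), 0)
  # GC count grows from zero toward the target band
  expect_gt(mean(tail(a$record$N_G, 5)), mean(head(a$record$N_G, 5)))

  # a one-step evolve equals a single neurogenesis_step
  set.seed(34)
  one <- evolve(net, env, p, n_steps = 1)
  set.seed(34)
  single <- neurogenesis_step(net, env, p)
  expect_identical(one$net$W_MG, single$net$W_MG)
})

test_that("scheduled interventions fire at their step", {
  p <- bulb_params(N_MC = 20, N_CC_odor = 20, N_CC_context = 0,
                   n_contexts = 0, N_conn_MG = 4, N_conn_GC = 2,
                   N_GC_aim = 20, g_init = 0.05)
  S <- gaussian_stimulus(data.frame(A = 1.8, x = 10, w = 4), 20)
  env <- environment_of(list(stimulus(S, params = p)))
  net <- new_network(p)
  marker <- new.env(); marker$hit <- NA
  set.seed(35)
  out <- evolve(net, env, p, n_steps = 6, interventions = list(
    list(step = 4, fn = function(net, params) { marker$hit <- 4; net },
         flags = list(freeze_g = TRUE))))
  expect_equal(marker$hit, 4)
  # g frozen from step 4 onward
  expect_equal(out$record$g[4], out$record$g[6])
})

test_that("surviving GCs are more resilient than the unselected newborn pool", {
  p <- bulb_params(N_MC = 40, N_CC_odor = 40, N_CC_context = 0,
                   n_contexts = 0, N_conn_MG = 6, N_conn_GC = 2,
                   N_GC_aim = 60, g_init = 0.05, g_gain = 0.03)
  S1 <- gaussian_stimulus(data.frame(A = 1.8, x = 12, w = 5), 40)
  S2 <- gaussian_stimulus(data.frame(A = 1.8, x = 28, w = 5), 40)
  env <- environment_of(list(stimulus(S1, params = p),
                             stimulus(S2, params = p)))
  set.seed(36)
  out <- evolve(new_network(p), env, p, n_steps = 60)
  tail_rec <- tail(out$record, 20)
  expect_gt(mean(tail_rec$mean_R_surv, na.rm = TRUE),
            mean(tail_rec$mean_R_new, na.rm = TRUE))
})
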