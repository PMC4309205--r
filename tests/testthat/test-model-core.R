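test_that("well-formed fixtures validate cleanly", {
  for (m in list(toggle_model(), negative_circuit_model(), step_model(),
                 self_activator_model(), constant_model(), th_demo_model())) {
    v <- validate_model(m)
    expect_length(v$errors, 0)
    expect_length(v$warnings, 0)
  }
})

test_that("validation reports threshold, regulator and range violations", {
  m <- toggle_model()

  bad_thr <- m
  bad_thr$interactions$threshold[bad_thr$interactions$source == "B"] <- 2L
  v <- validate_model(bad_thr)
  expect_match(v$errors, "threshold exceeds source max", all = FALSE)

  bad_reg <- m
  bad_reg$rules$A <- logical_rule("A", c("I", "C"), c(2L, 2L),
                                  rep(0L, 4L))
  v <- validate_model(bad_reg)
  expect_match(v$errors, "rule uses non-regulator", all = FALSE)

  bad_range <- m
  bad_range$rules$B <- logical_rule("B", "A", 2L, c(2L, 0L))
  v <- validate_model(bad_range)
  expect_match(v$errors, "out of range", all = FALSE)

  dup <- m
  dup$components <- rbind(dup$components, dup$components[2, ])
  v <- validate_model(dup)
  expect_match(v$errors, "duplicate component name", all = FALSE)
})

test_that("a declared interaction with no effect raises a warning by default", {
  m <- toggle_model()
  # declare a vestigial B -> B edge with a rule that ignores B
  m$components <- rbind(m$components,
                        data.frame(name = "C", max_level = 1L,
                                   is_input = FALSE))
  m$rules$C <- logical_rule("C", "B", 2L, c(0L, 0L))
  m$interactions <- rbind(m$interactions,
                          data.frame(source = "B", target = "C",
                                     threshold = 1L, sign = "unknown"))
  v <- validate_model(m)
  expect_length(v$errors, 0)
  expect_match(v$warnings, "non-functional interaction", all = FALSE)
  expect_length(validate_model(m, non_functional = "ignore")$warnings, 0)
})

test_that("knock-out reshapes the stable states as brute force predicts", {
  m <- apply_perturbation(toggle_model(), knock_out("B"))
  got <- state_keys(oracle_stable_states(m))
  # order I, A, B: (I=0,A=0,B=0) and (I=1,A=1,B=0)
  expect_identical(got, c("0,0,0", "1,1,0"))
  exp_pkg <- expand_contexts(stable_states(m))
  expect_identical(state_keys(as.matrix(exp_pkg[c("I", "A", "B")])), got)
})

test_that("ectopic expression forces a constant rule regardless of context", {
  m <- apply_perturbation(toggle_model(), ectopic("A", 1L))
  expect_identical(m$rules$A$regulators, character(0))
  expect_identical(m$rules$A$outputs, 1L)
  # and the original model is unchanged
  expect_length(toggle_model()$rules$A$regulators, 2L)
})

test_that("edge suppression clamps the source below its threshold", {
  m <- apply_perturbation(toggle_model(), edge_suppression("B", "A"))
  # K_A becomes [I=1]: B is no longer a regulator of A
  expect_identical(m$rules$A$regulators, "I")
  expect_identical(m$rules$A$outputs, c(0L, 1L))
  expect_false(any(m$interactions$source == "B" &
                     m$interactions$target == "A"))
})

test_that("perturbations are validated and conflicts rejected", {
  m <- toggle_model()
  expect_error(apply_perturbation(m, knock_out("Z")), "unknown target")
  expect_error(apply_perturbation(m, list(knock_out("B"), ectopic("B", 1L))),
               "conflicting")
  expect_error(apply_perturbation(m, knock_out("I")), "input components")
  expect_error(apply_perturbation(m, ectopic("A", 5L)), "out of range")
})

test_that("knock-out and ectopic perturbations are idempotent", {
  m <- toggle_model()
  for (p in list(knock_out("B"), ectopic("A", 1L))) {
    once <- apply_perturbation(m, p)
    twice <- apply_perturbation(once, p)
    expect_true(models_equivalent(once, twice))
  }
})

test_that("interaction functionality derives signs and contexts by sweep", {
  m <- toggle_model()
  fr <- interaction_functionality(m, "B", "A")
  expect_true(fr$functional)
  expect_identical(fr$derived_sign, "inhibition")
  expect_identical(fr$context, data.frame(I = 1L))

  fr <- interaction_functionality(m, "I", "A")
  expect_identical(fr$derived_sign, "activation")
  expect_identical(fr$context, data.frame(B = 0L))

  expect_error(interaction_functionality(m, "A", "I"), "unknown interaction")
})

test_that("every declared interaction of the fixtures is functional at theta", {
  for (m in list(toggle_model(), negative_circuit_model(), step_model(),
                 th_demo_model())) {
    tab <- functionality_table(m)
    expect_true(all(tab$functional))
    expect_true(all(tab$n_contexts >= 1L))
    # derived sign agrees with the declared (rule-derived) interaction sign
    expect_identical(tab$derived_sign, m$interactions$sign)
  }
})

test_that("functional interactions always have a witnessing threshold pair", {
  for (seed in 1:20) {
    m <- draw_battery_model(seed)
    tab <- functionality_table(m)
    card <- ocard(m)
    for (i in seq_len(nrow(tab))) {
      fr <- interaction_functionality(m, tab$source[i], tab$target[i],
                                      tab$threshold[i])
      expect_true(fr$functional)
      # verify one witness directly against the rule
      rule <- m$rules[[tab$target[i]]]
      ctx_v <- unlist(fr$context[1, , drop = FALSE])
      hi <- lo <- c(ctx_v, setNames(0L, tab$source[i]))
      hi[tab$source[i]] <- tab$threshold[i]
      lo[tab$source[i]] <- tab$threshold[i] - 1L
      expect_false(eval_rule(rule, hi) == eval_rule(rule, lo))
    }
  }
})

test_that("the toggle circuit is positive with context I=1", {
  cf <- circuit_functionality(toggle_model(), c("A", "B"))
  expect_identical(cf$sign, "positive")
  expect_true(cf$functional)
  expect_identical(cf$context, data.frame(I = 1L))
})

test_that("a self-activator is a positive circuit functional everywhere", {
  cf <- circuit_functionality(self_activator_model(), "C")
  expect_identical(cf$sign, "positive")
  expect_true(cf$functional)
  expect_identical(ncol(cf$context), 0L)
  expect_identical(nrow(cf$context), 1L)
})

test_that("fixing the input at 0 kills the toggle circuit's context", {
  m <- fix_inputs(toggle_model(), c(I = 0L))
  cf <- circuit_functionality(m, c("A", "B"))
  expect_false(cf$functional)
  expect_identical(nrow(cf$context), 0L)
})

test_that("circuit sign is the parity of inhibitions along the cycle", {
  cf <- circuit_functionality(negative_circuit_model(), c("A", "B"))
  expect_identical(cf$sign, "negative")  # one inhibition, one activation
  expect_error(circuit_functionality(toggle_model(), c("A", "I")),
               "elementary cycle")
  expect_error(circuit_functionality(toggle_model(), c("A", "A")),
               "repeated node")
})

test_that("a dead circuit edge leaves the dynamics unchanged when suppressed", {
  # with I fixed at 0 the A->B->A circuit is non-functional; suppressing
  # B->A must then not change the stable-state count
  m <- fix_inputs(toggle_model(), c(I = 0L))
  expect_false(circuit_functionality(m, c("A", "B"))$functional)
  base <- state_keys(oracle_stable_states(m))
  supp <- apply_perturbation(toggle_model(), edge_suppression("B", "A"))
  supp0 <- fix_inputs(supp, c(I = 0L))
  expect_identical(state_keys(oracle_stable_states(supp0)), base)
})

test_that("find_circuits enumerates elementary cycles deterministically", {
  m <- toggle_model()
  expect_identical(find_circuits(m), list(c("A", "B")))
  expect_identical(find_circuits(self_activator_model()), list("C"))
  expect_identical(find_circuits(th_demo_model(), max_length = 2),
                   find_circuits(th_demo_model(), max_length = 2))
})
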