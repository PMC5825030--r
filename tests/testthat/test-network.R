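test_that("reference network is flow-balanced with 6500 ml/min left-heart output", {
  net <- ref_net()
  expect_equal(left_heart_output(net), 6500)
  bal <- check_flow_balance(net)
  expect_true(all(abs(bal$inflow - bal$outflow) /
                    pmax(bal$inflow, 1e-12) <= 1e-6))
  # organs modeled separately from the classic lumped splanchnic compartment
  expect_true(all(c("stomach", "spleen", "pancreas", "myocardium") %in%
                    net$compartments$name))
  # systemic inflows (everything fed by the two aortic segments) total the CO
  aortic <- net$edges$from %in% c("ascending_aorta", "abdominal_aorta")
  systemic <- net$edges$to[aortic] != "abdominal_aorta"
  expect_equal(sum(net$edges$flow[aortic][systemic]), 6500)
})

test_that("circulation graph is one strongly connected loop", {
  net <- ref_net()
  reach <- function(start) {
    seen <- start
    repeat {
      nxt <- unique(net$edges$to[net$edges$from %in% seen])
      new <- setdiff(nxt, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    seen
  }
  all_names <- net$compartments$name
  # every compartment reachable from the injection-site vein, and the vein
  # reachable from every compartment (one closed loop)
  expect_setequal(reach("peripheral_vein"), all_names)
  for (nm in all_names)
    expect_true("peripheral_vein" %in% reach(nm))
})

test_that("weight scaling is proportional and preserves balance", {
  net <- ref_net()
  expect_equal(scale_to_weight(net, 60), net)
  dbl <- scale_to_weight(net, 120)
  expect_equal(dbl$edges$flow, net$edges$flow * 2)
  expect_equal(dbl$compartments$v_iv, net$compartments$v_iv * 2)
  expect_equal(dbl$compartments$v_ec, net$compartments$v_ec * 2)
  s65 <- scale_to_weight(net, 65)
  expect_equal(left_heart_output(s65), 6500 * 65 / 60)
  expect_silent(check_flow_balance(s65))
  expect_error(scale_to_weight(net, 0), "positive")
})

test_that("cardiac-output adjustment rescales flows only", {
  net <- ref_net()
  expect_equal(adjust_to_cardiac_output(net, 6500), net)
  half <- adjust_to_cardiac_output(net, 3250)
  expect_equal(half$edges$flow, net$edges$flow / 2)
  expect_equal(half$compartments$v_iv, net$compartments$v_iv)
  expect_equal(left_heart_output(half), 3250)
  expect_silent(check_flow_balance(half))
  expect_error(adjust_to_cardiac_output(net, -1), "positive")
  # scaling and adjustment reach the same network whatever the order, once
  # both paths are normalized to the same target output
  a <- adjust_to_cardiac_output(scale_to_weight(net, 80), 4200)
  b <- adjust_to_cardiac_output(
    scale_to_weight(adjust_to_cardiac_output(net, 4200), 80), 4200)
  expect_equal(a$edges$flow, b$edges$flow)
  expect_equal(a$compartments$v_iv, b$compartments$v_iv)
})

test_that("malformed parameter files name the offending compartment", {
  comp <- ref_net()$compartments
  comp$blood_flow[comp$name == "liver"] <- -5
  f <- tempfile(fileext = ".tsv")
  write.table(comp, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(build_reference_network(compartment_file = f), "liver")
  comp2 <- ref_net()$compartments
  comp2$n_sub[comp2$name == "lungs"] <- 0
  write.table(comp2, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(build_reference_network(compartment_file = f), "lungs")
})
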