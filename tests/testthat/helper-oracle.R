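# Frozen oracle values, computed term by term at 50-digit precision with an
# independent symbolic evaluator before the implementation was written.
ref_params <- hp_params_reference()

oracle_q45 <- 0.045280628485020156
oracle_q50 <- 0.060238470904006971
oracle_terms45 <- c(childhood = 7.36043648336425597e-4,
                    hump = 3.38061337272304115e-8,
                    senescent = 4.45445510305500036e-2)
# sum((1 - qhat/q)^2) over ages (50, 60, 70) with observed q (.05, .10, .20)
oracle_toy_rel_sse <- 0.057423822235073656
# logistic midpoint -log(G)/log(H) for G = 2.9952e-3, H = 1.0629
oracle_midpoint_age <- 95.256507568703214

make_traj <- function(age, lx, dx, ex, step = 1, mode = "replication") {
  tr <- data.frame(age = age, lx = lx, dx = dx, ex = ex)
  attr(tr, "step") <- step
  attr(tr, "mode") <- mode
  attr(tr, "l0") <- lx[1]
  class(tr) <- c("cohort_trajectory", "data.frame")
  tr
}
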