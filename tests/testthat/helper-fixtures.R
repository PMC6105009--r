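default_task <- function(seed = 101) generate_task(isp_config(seed = seed))

sim_subject <- function(task = default_task(), model_id = "2HGF-RelPE+IrrelBias",
                        omega = -2, sigma2_0 = 0.05, beta0 = 6.25,
                        beta1 = 0.2, beta2 = 0.05, beta3 = 0, beta4 = 0.03,
                        beta5 = 0, beta6 = 0.07, zeta = 0.04, seed = 7,
                        ...) {
  simulate_subject(
    task, model_id, learn_params(omega = omega, sigma2_0 = sigma2_0),
    resp_params(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                beta4 = beta4, beta5 = beta5, beta6 = beta6, zeta = zeta),
    seed = seed, ...)
}

quiet_fit <- function(...) suppressWarnings(map_fit(...))
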