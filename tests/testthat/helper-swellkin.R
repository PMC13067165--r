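# Shared fixture builders. All synthetic data is generated in code with
# fixed seeds; no files are read.

make_curve <- function(times, k, a_star, b_star) {
  tibble::tibble(time_h = times,
                 swelling = eval_swelling_eq(times, k, a_star, b_star))
}

# random positive-parameter sets for property loops
random_params <- function(n, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    k = runif(n, 0.01, 2),
    a_star = runif(n, 0.05, 5),
    b_star = runif(n, 0.05, 30)
  )
}
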