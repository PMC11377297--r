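## Shared fixtures: the experimental pulling protocol, the lambda-DNA
## tether, and the fitted parameter pairs for each pulling scenario with
## their 90% confidence intervals (used as recovery targets).

lambda_wlc <- function() wlc_params(persistence_nm = 50, contour_nm = 16320)
plasmid_wlc <- function() wlc_params(persistence_nm = 50, contour_nm = 2448)

exp_protocol <- function(seed = NULL, dt_s = 0.01) {
  pulling_protocol(velocity_um_per_s = 0.16, dt_s = dt_s,
                   anchor_mean_um = 8.8, anchor_sd_um = 0.5, seed = seed)
}

head_bond <- function() bond_model(0.0027, 1.23)
hinge_bond <- function() bond_model(0.0025, 1.61)
headx_bond <- function() bond_model(0.0022, 1.22)
strong_bond <- function() bond_model(2.7e-5, 0.8)

## scenario parameter pairs with their reported 90% confidence intervals;
## recovery tests require fits to land inside these
scenario_truth <- list(
  head = list(k0 = 0.0027, delta = 1.23,
              ci_k0 = c(0.0023, 0.0036), ci_delta = c(1.17, 1.29)),
  hinge = list(k0 = 0.0025, delta = 1.61,
               ci_k0 = c(0.0016, 0.0034), ci_delta = c(1.47, 1.71)),
  head_crosslinked = list(k0 = 0.0022, delta = 1.22,
                          ci_k0 = c(0.0011, 0.0035), ci_delta = c(1.1, 1.35)),
  peak70 = list(k0 = 2.7e-5, delta = 0.8,
                ci_k0 = c(1.6e-5, 3.9e-5), ci_delta = c(0.77, 0.83))
)

## Marko-Siggia force written out independently of the package's internals
ms_force <- function(L, P, L0, kBT = 4.114) {
  (kBT / P) * (1 / (4 * (1 - L / L0)^2) - 1 / 4 + L / L0)
}

quiet <- function(expr) suppressMessages(expr)
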