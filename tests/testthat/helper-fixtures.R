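# Shared fixtures: canonical models per case and the frozen classification
# matrices the two indistinguishability settings must reproduce.

default_params <- cstr_parameters()
default_true_kin <- true_kinetics()

model_for_case <- function(case_id, params = default_params) {
  cr <- enumerate_cases()[case_id, ]
  case_model(cr, params, default_true_kin)
}

subcases_of <- function(case_id) {
  if (enumerate_cases()$output_index[case_id] == 1L)
    c("generic", "washout-ic", "washout-asymptotic")
  else "generic"
}

compact_labels <- function(cl) {
  enc <- function(x) paste(ifelse(is.na(x), "-", ifelse(x, "Y", "N")),
                           collapse = "")
  c(obs = enc(cl$observable), det = enc(cl$detectable))
}

# Entity order nu1, nu2, nu3, delta_delta; "-" marks measured / not applicable.
# With the unknown-input difference present:
expected_with_uncertainty <- list(
  "1:generic" = c(obs = "NN-N", det = "YY-Y"),
  "2:generic" = c(obs = "-NNN", det = "-YYY"),
  "2:washout-ic" = c(obs = "-NNY", det = "-YYN"),
  "2:washout-asymptotic" = c(obs = "-NNN", det = "-YYN"),
  "3:generic" = c(obs = "Y-YY", det = "Y-YY"),
  "4:generic" = c(obs = "YY-Y", det = "YY-Y"),
  "5:generic" = c(obs = "-NNN", det = "-YYY"),
  "5:washout-ic" = c(obs = "-NNY", det = "-YYY"),
  "5:washout-asymptotic" = c(obs = "-NNN", det = "-YYY"),
  "6:generic" = c(obs = "N-NN", det = "Y-YY"),
  "7:generic" = c(obs = "-YYY", det = "-YYY"),
  "7:washout-ic" = c(obs = "-YYN", det = "-YYN"),
  "7:washout-asymptotic" = c(obs = "-YYN", det = "-YYN"),
  "8:generic" = c(obs = "Y-YY", det = "Y-YY"),
  "9:generic" = c(obs = "YY-Y", det = "YY-Y")
)

# Uncertainty-free comparison setting (fourth entity not applicable):
expected_without_uncertainty <- list(
  "1:generic" = c(obs = "YN--", det = "YY--"),
  "2:generic" = c(obs = "-NY-", det = "-YY-"),
  "2:washout-ic" = c(obs = "-NN-", det = "-YY-"),
  "2:washout-asymptotic" = c(obs = "-NN-", det = "-YY-"),
  "3:generic" = c(obs = "Y-Y-", det = "Y-Y-"),
  "4:generic" = c(obs = "YY--", det = "YY--"),
  "5:generic" = c(obs = "-YN-", det = "-YY-"),
  "5:washout-ic" = c(obs = "-NN-", det = "-YY-"),
  "5:washout-asymptotic" = c(obs = "-NN-", det = "-YY-"),
  "6:generic" = c(obs = "Y-N-", det = "Y-Y-"),
  "7:generic" = c(obs = "-YY-", det = "-YY-"),
  "7:washout-ic" = c(obs = "-NN-", det = "-YY-"),
  "7:washout-asymptotic" = c(obs = "-NN-", det = "-YY-"),
  "8:generic" = c(obs = "Y-Y-", det = "Y-Y-"),
  "9:generic" = c(obs = "YY--", det = "YY--")
)

# consolidated per-state coding (geometric | with-uncertainty | without)
expected_consolidated <- rbind(
  c("UO", "UO", "M", "D", "D", "M", "O", "D", "M"),
  c("M", "UO", "UO", "M", "D", "D", "M", "D", "O/D"),
  c("O", "M", "O", "O", "M", "O", "O", "M", "O"),
  c("O", "O", "M", "O", "O", "M", "O", "O", "M"),
  c("M", "UO", "UO", "M", "D", "D", "M", "O/D", "D"),
  c("UO", "M", "UO", "D", "M", "D", "O", "M", "D"),
  c("M", "O", "O", "M", "O", "O", "M", "O/D", "O/D"),
  c("O", "M", "O", "O", "M", "O", "O", "M", "O"),
  c("O", "O", "M", "O", "O", "M", "O", "O", "M")
)

geometric_expected <- c("not-observable", "not-observable", "observable",
                        "observable", "not-observable", "not-observable",
                        "observable", "observable", "observable")
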