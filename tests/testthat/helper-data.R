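# Shared fixtures, built in code.

# Construct a report tibble from parallel vectors; drugs/reactions may be
# ";"-separated multi-sets.
make_reports <- function(case_id, sex, drugs, reactions) {
  tibble::tibble(
    case_id = case_id,
    sex = sex,
    drugs = lapply(strsplit(drugs, ";", fixed = TRUE), sort),
    reactions = lapply(strsplit(reactions, ";", fixed = TRUE), sort)
  )
}

# Six-report toy set used for hand-enumerated counting checks:
# (D,X,m) (D,Y,m) (D,X,f) (E,X,m) (E,Y,f) (E,Z,m)
toy6_reports <- function() {
  make_reports(
    case_id = sprintf("c%d", 1:6),
    sex = c("male", "male", "female", "male", "female", "male"),
    drugs = c("D", "D", "D", "E", "E", "E"),
    reactions = c("X", "Y", "X", "X", "Y", "Z")
  )
}

# Write the toy set as a long CSV and return the path.
toy6_csv <- function(path = tempfile(fileext = ".csv")) {
  suppressMessages(write_icsr(toy6_reports(), path, format = "long_csv"))
  path
}

# Small planted-signal config shared by recovery-style tests: a rare drug
# carrying a strong male signal.
recovery_config <- function(n_reports, seed, rho_male = 8, rho_female = 1) {
  sim_config(
    n_reports,
    signals = planted_signal("drug_20", "seminoma",
                             rho_male = rho_male, rho_female = rho_female),
    seed = seed
  )
}
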