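# Shared fixtures built in code.

# A patient record with every field at a comfortably plausible value.
plausible_record <- function(id = "P001", disease = "COPD",
                             support_mode = "PS") {
  data.frame(patient_id = id, disease = disease,
             core_body_temperature = 36.8, pulse = 82,
             arterial_systolic_pressure = 118, diastolic_blood_pressure = 74,
             peep = 4, pso2 = 95, ph = 7.40, po2 = 92, pco2 = 38,
             bicarbonate = 24, frequency = 14, tidal_volume = 480,
             fio2 = 0.21, support_mode = support_mode,
             stringsAsFactors = FALSE)
}

# A small fully-populated cohort of distinct plausible records.
tiny_cohort <- function(n = 3) {
  rows <- lapply(seq_len(n), function(i) {
    r <- plausible_record(sprintf("P%03d", i),
                          disease = c("COPD", "ARDS", "CVD")[(i - 1) %% 3 + 1],
                          support_mode = c("PS", "VS")[(i - 1) %% 2 + 1])
    r$pulse <- r$pulse + i
    r$pco2 <- r$pco2 + i / 2
    r$tidal_volume <- r$tidal_volume + 10 * i
    r
  })
  do.call(rbind, rows)
}

# Central finite-difference gradient of the sum-of-squares loss.
fd_gradient <- function(model, X, Y, h = 1e-6) {
  theta <- flatten_params(model)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (sse_loss(unflatten_params(model, tp), X, Y) -
       sse_loss(unflatten_params(model, tm), X, Y)) / (2 * h)
  }, 0)
}

# Central finite-difference Jacobian of the network outputs, rows ordered
# like mlp_residuals (samples within output).
fd_jacobian <- function(model, X, h = 1e-6) {
  theta <- flatten_params(model)
  cols <- lapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    as.vector(mlp_forward(unflatten_params(model, tp), X) -
                mlp_forward(unflatten_params(model, tm), X)) / (2 * h)
  })
  do.call(cbind, cols)
}

# Reference printed proportions as plain columns (for acceptance checks).
printed_columns <- function() reference_finding_probabilities()
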