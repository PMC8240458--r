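# Shared fixtures: small media and ground-truth helpers, all built in code.

# True intensity-transmission constants A_mn * A_R * cos(theta_mn - phi_R)
# for one output row, computed directly from the medium.
truth_rvit <- function(tm, target_index) {
  row <- tm$elements[target_index, ]
  s <- sum(row)
  Mod(row) * Mod(s) * cos(wrap_phase(Arg(row) - Arg(s)))
}

# Hand-built medium with one output row of prescribed phases (unit
# amplitudes), padded with extra rows so that PBR is defined.
tm_from_phases <- function(phases, n_outputs = 8, target_row = 1, seed = 99) {
  tm <- sample_tm(length(phases), n_outputs, seed = seed)
  tm$elements[target_row, ] <- exp(1i * phases)
  tm
}

# Run the bundled command-line script in a child R process, inheriting the
# current library paths.
run_cli <- function(args) {
  script <- system.file("cli", "fibrefocus.R", package = "fibrefocus")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(output = out, status = attr(out, "status") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
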