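# Classed conditions so callers (and the CLI) can map failures to categories.

stop_gcctwin <- function(subclass, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(paste0("gcctwin_", subclass), "gcctwin_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

# subclasses in use:
#   parse_error     malformed input file (names offending line/cell)
#   field_error     required VCF FORMAT field absent
#   schema_error    required column missing
#   integrity_error duplicate ids / inconsistent family metadata
#   input_error     non-finite or out-of-range values
#   degenerate_error zero-variance input
#   sample_size_error too few observations
#   resolution_error permutation count cannot resolve the requested quantile
#   structure_error family larger than a twin pair
#   matrix_error    covariance matrix not PSD
#   convergence_error REML failed to converge
#   rank_error      collinear / singular design
#   join_error      empty sample intersection
#   config_error    invalid configuration value
#   misuse_error    operation called outside its study design
#   usage_error     CLI usage problem (exit code 2)
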