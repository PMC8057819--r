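# Builders for small two-taxon abundance/biomass fixtures.
#
# `spec` is a data.frame with columns inoculum, replicate, environment, f
# (abundance of taxon "TaxA"; "TaxB" gets 1 - f) and optionally b (biomass).
make_tables <- function(spec) {
  spec$b <- if (is.null(spec$b)) 1 else spec$b
  sid <- paste(spec$inoculum, gsub("+", ".", spec$environment, fixed = TRUE),
               spec$replicate, sep = "_")
  abundance <- data.frame(
    sample_id = rep(sid, each = 2),
    inoculum = rep(spec$inoculum, each = 2),
    replicate = rep(spec$replicate, each = 2),
    environment = rep(spec$environment, each = 2),
    taxon = rep(c("TaxA", "TaxB"), nrow(spec)),
    taxon_level = "family",
    rel_abundance = as.vector(rbind(spec$f, 1 - spec$f)))
  list(abundance = abundance,
       biomass = data.frame(sample_id = sid, biomass = spec$b))
}

# Full 2-inocula x 4-replicate design for one pair: per-environment TaxA
# fractions given as vectors recycled over (inoculum, replicate).
full_design_tables <- function(f1, f2, f12, cs1 = "cs1", cs2 = "cs2",
                               b1 = 1, b2 = 1, b12 = 1,
                               inocula = c("I1", "I2"), replicates = 4) {
  grid <- expand.grid(replicate = seq_len(replicates), inoculum = inocula,
                      stringsAsFactors = FALSE)
  env <- pair_label(cs1, cs2)
  spec <- rbind(
    data.frame(grid, environment = cs1, f = rep_len(f1, nrow(grid)),
               b = rep_len(b1, nrow(grid))),
    data.frame(grid, environment = cs2, f = rep_len(f2, nrow(grid)),
               b = rep_len(b2, nrow(grid))),
    data.frame(grid, environment = env, f = rep_len(f12, nrow(grid)),
               b = rep_len(b12, nrow(grid))))
  make_tables(spec)
}

two_class_map <- c(cs1 = "sugar", cs2 = "acid",
                   glucose = "sugar", fructose = "sugar",
                   succinate = "acid", fumarate = "acid")
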