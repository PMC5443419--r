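# Regenerates the packaged spectral tables under inst/extdata/.
#
# The tables are smooth parametric/spline stand-ins anchored to widely cited
# literature values (hemoglobin extinction compendia; the oxidised-minus-
# reduced cytochrome-c-oxidase difference band centred near 830 nm; adult-head
# DPF curves; per-tissue optical properties used in head modelling). They are
# synthetic reconstructions, not digitized copies, and are labelled as such in
# each file header. Run from the package root: Rscript data-raw/make_tables.R

grid <- seq(700, 1000, by = 2)

write_spec <- function(path, wl, value, units, comment) {
  con <- file(path, "w")
  writeLines(c(
    paste0("# ", comment),
    "# synthetic: smooth parametric stand-in anchored to published literature values, not a digitized copy",
    paste0("# units: ", units),
    "wavelength_nm,value"
  ), con)
  write.table(data.frame(wl, signif(value, 6)), con, sep = ",",
              row.names = FALSE, col.names = FALSE)
  close(con)
}

# Oxy-hemoglobin: monotone rise through the NIR window, shallow peak ~920 nm.
hbo2_anchor_wl <- c(700, 720, 740, 760, 780, 800, 820, 840, 860, 880, 900,
                    920, 950, 1000)
hbo2_anchor    <- c(0.29, 0.33, 0.45, 0.59, 0.71, 0.81, 0.91, 1.02, 1.10,
                    1.16, 1.20, 1.24, 1.22, 1.10)
hbo2 <- splinefun(hbo2_anchor_wl, hbo2_anchor, method = "monoH.FC")(grid)

# Deoxy-hemoglobin: local band near 758 nm, broad minimum ~860 nm.
hhb_anchor_wl <- c(700, 715, 730, 745, 758, 770, 780, 790, 800, 815, 830,
                   850, 870, 900, 950, 1000)
hhb_anchor    <- c(1.79, 1.55, 1.35, 1.38, 1.58, 1.31, 1.08, 0.95, 0.88,
                   0.81, 0.76, 0.73, 0.72, 0.73, 0.80, 0.84)
hhb <- splinefun(hhb_anchor_wl, hhb_anchor, method = "fmm")(grid)

# Oxidised-minus-reduced CCO difference spectrum: broad band centred at 830 nm.
oxcco <- 0.35 +
  2.00 * exp(-0.5 * ((grid - 830) / 58)^2) +
  0.25 * exp(-0.5 * ((grid - 740) / 40)^2)

write_spec("inst/extdata/extinction_hbo2_synthetic.csv", grid, hbo2,
           "mM^-1 cm^-1 (base-10 specific absorption)",
           "oxy-hemoglobin (HbO2) specific absorption spectrum")
write_spec("inst/extdata/extinction_hhb_synthetic.csv", grid, hhb,
           "mM^-1 cm^-1 (base-10 specific absorption)",
           "deoxy-hemoglobin (HHb) specific absorption spectrum")
write_spec("inst/extdata/extinction_oxcco_diff_synthetic.csv", grid, oxcco,
           "mM^-1 cm^-1 (base-10 specific absorption, oxidised-minus-reduced difference)",
           "cytochrome-c-oxidase oxidised-minus-reduced difference spectrum")

# Adult-head DPF wavelength dependence: slow decline across the NIR window.
dpf_anchor_wl <- c(700, 740, 780, 810, 850, 900, 950, 1000)
dpf_anchor    <- c(6.55, 6.30, 6.00, 5.80, 5.60, 5.25, 5.00, 4.80)
dpf <- splinefun(dpf_anchor_wl, dpf_anchor, method = "monoH.FC")(grid)
write_spec("inst/extdata/dpf_adult_head_synthetic.csv", grid, dpf,
           "dimensionless (differential pathlength factor)",
           "adult-head differential pathlength factor vs wavelength")

# Per-tissue baseline optical properties. mua rises mildly with wavelength
# (water tail); musp declines ~ (lambda/800)^-1.
tissues <- data.frame(
  tissue   = c("scalp", "skull", "csf", "gm", "wm"),
  mua800   = c(0.0180, 0.0120, 0.0035, 0.0180, 0.0150),
  musp800  = c(0.7500, 0.9000, 0.2500, 0.8500, 1.1000),
  mua_slope = c(0.10, 0.08, 0.05, 0.12, 0.10)  # fractional rise per 160 nm
)
knots <- seq(700, 1000, by = 50)
rows <- do.call(rbind, lapply(seq_len(nrow(tissues)), function(i) {
  t <- tissues[i, ]
  data.frame(
    tissue = t$tissue, wavelength_nm = knots,
    mua_mm  = signif(t$mua800 * (1 + t$mua_slope * (knots - 800) / 160), 5),
    musp_mm = signif(t$musp800 * (800 / knots), 5)
  )
}))
con <- file("inst/extdata/tissue_optics_synthetic.csv", "w")
writeLines(c(
  "# per-tissue baseline optical properties for head-like phantoms",
  "# synthetic: literature-plausible defaults, not fitted values; override via load_tissue_optics()",
  "# units: mua_mm mm^-1, musp_mm mm^-1 (reduced scattering)",
  "tissue,wavelength_nm,mua_mm,musp_mm"
), con)
write.table(rows, con, sep = ",", row.names = FALSE, col.names = FALSE,
            quote = FALSE)
close(con)

cat("wrote", length(grid), "rows per spectral table\n")
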