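#!/usr/bin/env Rscript
# Pump-induced alignment on the detector: render a synthetic 2-D image with
# isotropic + P2 anisotropic components, decompose it back, and verify the
# round trip.
#
# Writes: results/anisotropy/decomposition.tsv

library(trxkin)
dir.create("results/anisotropy", recursive = TRUE, showWarnings = FALSE)

geom <- detector_geometry()   # 64x64 stand-in for the megapixel detector
qr <- detector_qrange(geom)
message(sprintf("detector covers q in [%.2f, %.2f] 1/A at %.1f keV",
                qr[1], qr[2], geom$energy_kev))

S0 <- function(q) 3 * exp(-0.4 * q) + 0.3 * sin(1.5 * q)
S2 <- function(q) 0.5 * exp(-0.2 * q) * cos(q)
img <- render_detector_image(S0, S2, geom, noise = 0.01, seed = 5)
dec <- decompose_iso_aniso(img, geom)

ok <- !dec$flagged
tab <- data.frame(q = dec$q, S0 = dec$S0, S0_sigma = dec$sigma0,
                  S2 = dec$S2, S2_sigma = dec$sigma2, n_pixels = dec$n,
                  flagged = dec$flagged)
write.table(format(tab, digits = 6), "results/anisotropy/decomposition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d of %d q-bins usable (corner bins flagged for weak angular coverage)",
                sum(ok), length(ok)))
message(sprintf("S0 recovered within %.3f, S2 within %.3f (RMS, noise 0.01)",
                sqrt(mean((dec$S0[ok] - S0(dec$q[ok]))^2)),
                sqrt(mean((dec$S2[ok] - S2(dec$q[ok]))^2))))
message("the isotropic component is what the kinetic analysis consumes;")
message("the anisotropic channel is retrieved but not analysed further")
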