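{
  "description": "SYNTHETIC example trait table. Species labels are ten temperate deciduous trees commonly used in diversity experiments; trait VALUES are plausible but fabricated for demonstration and testing only — do not use for science.",
  "units": {
    "leaf_out_doy": "day of year",
    "sla_mm2_mg": "specific leaf area, mm^2/mg",
    "max_height_m": "maximum tree height, m",
    "wood_density_g_cm3": "wood density, g/cm^3",
    "leaf_cn_ratio": "leaf C:N mass ratio, dimensionless",
    "seed_mass_mg": "seed mass, mg"
  }
}
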