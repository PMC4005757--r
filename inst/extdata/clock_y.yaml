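# Dating clock configuration.
#
# generation_years: years per male generation (25 reproduces the
#   generation-to-year arithmetic of standard published dating tables).
# dating_loci: the 8 Y-STR loci used by the variance estimator; the set
#   should be the markers with the highest duration of linearity for the
#   panel at hand (Busby-style selection).  The set below is a documented
#   placeholder for the Yfiler panel -- edit before dating real data.
# locus_rates: mutations/locus/generation on the pedigree (father-son)
#   scale of Ballantyne et al. (2010).  Placeholder values of the right
#   order of magnitude -- edit to the published locus estimates you use.
# hvs_rate_years_per_mutation: years per HVS-I mutation (Soares-style
#   calibration).  No default is ever assumed by the code.
generation_years: 25
hvs_rate_years_per_mutation: 9058
dating_loci: [DYS19, DYS389I, DYS389b, DYS390, DYS391, DYS392, DYS393, DYS439]
locus_rates:
  DYS19: 0.0023
  DYS389I: 0.0025
  DYS389b: 0.0028
  DYS390: 0.0021
  DYS391: 0.0026
  DYS392: 0.0004
  DYS393: 0.0011
  DYS439: 0.0050
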