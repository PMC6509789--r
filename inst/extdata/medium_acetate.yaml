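# Photoheterotrophic acetate medium for the toy phototroph: measured acetate
# uptake, unlimited light; CO2 uptake stays closed (export only).
exchanges:
  EX_ac: {uptake_max: 1.96}
  EX_photon: {uptake_max: unlimited}
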