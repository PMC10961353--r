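# Molar extinction coefficients for hemoglobin chromophores, pinned so that
# concentration estimates are bit-reproducible across package versions.
# Values compiled from a standard published tabulation of hemoglobin spectra;
# units: cm^-1 / (mol/L). Conversion to (uM mm)^-1 is 1e-7 per coefficient.
version: 1
units: cm-1_per_M
wavelengths_nm: [735, 850]
hbo: [450.0, 1058.0]
hbr: [1050.0, 691.3]
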