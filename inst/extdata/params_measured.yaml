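# Measured drive parameters (defaults used throughout the package):
# average drive conversion 76.7%, total germline resistance 22.2%,
# embryo cut rate 52.2%, off-target germline cut rate 1 in drive
# carriers, 50% of founder-carrier off-target sites already disrupted.
conversion_female: 0.767
conversion_male: 0.767
germline_resistance_total: 0.222
embryo_cut_rate: 0.522
relative_r1_rate: 0.0
offtarget_germline_cut_rate: 1.0
initial_offtarget_cut_fraction: 0.5
cas9_present: yes
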