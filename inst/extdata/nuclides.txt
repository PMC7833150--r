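# Supported radionuclides.  Noble gases carry no ground-deposition source.
# columns: nuclide  noble_gas  progeny_note
85Kr yes -
132Te no -
131I no -
132I no -
133I no -
133Xe yes -
134Cs no -
136Cs no -
137Cs no includes_137mBa_in_equilibrium
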