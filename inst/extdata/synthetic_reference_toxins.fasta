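>synthetic_ref_SF1 synthetic reference toxin (C-C-CC-C pattern)
GYTVYSHYIPCEGKSWECGTYYGDAPCCVHGRNEKWYKNCSARADEDMTWKKAP
>synthetic_ref_SF2 synthetic reference toxin (C-C-C-CC-C pattern)
EADYNQFACMEKFQHIHTDIICKHKWCETWIYELCCIVYPTNCGEEKI
>synthetic_ref_SF3 synthetic reference toxin (C-C-CC-C-C-C pattern)
HKTMYTCQVDRLSILFCHVPHIMAINIIECCIYWMSSFLQDQGYCIFRFERNNTAMPKHCSQPWLLYDCREQN
>synthetic_ref_SF4 synthetic reference toxin (C-C-CC-C-C-C-C pattern)
WGNQHASHQCNFNQTKCGMFDMNVTCCYWYANRCEEPREIYMRCSPPDMCLLQPCYP
>synthetic_ref_SF5 synthetic reference toxin (C-C-C-CC-C-C-C pattern)
QEIPYDHCWLKHKPCEDWTTKIQCHINMPECCDARWKAGGCKLKARNCWLWNWSTEWCVFEN
>synthetic_ref_SF6 synthetic reference toxin (C-C-C-C-CC-C-C pattern)
VQPKMLCVDWCWKSPVTPQMGCGDRAYCGQQSFVFPLCCAHNTFCYDVICIDIF
>synthetic_ref_SF7 synthetic reference toxin (C-C-C-C-C-CC-C pattern)
IVPIDTPGSPSCPPTFHVHLNIPPLCVRVGAPMKFPICAIPPFACEMRGHFEMECRNVGYVYCCTKPKKQFTCQHR
>synthetic_ref_SF8 synthetic reference toxin (C-C-CC-C-C-C-C-C-C pattern)
HALTICHFSVTPAVCTVRISLNCCEELPHEIDCMTANACGRAWECYHANAMNQCMRKIDMGRQWLCHVEMNGVLIMVICS
ESN
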