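atc_code,member_of
N05BA01,
N05BA02,
N05BA06,
N05BA12,
N05CD02,
N05CF01,
N05CF02,
N06AA09,
N06AA10,
N06AB03,
N06AB04,
N06AB05,
M01AB01,
M01AB05,
M01AE01,
M01AE02,
M01AH01,
C02AB01,
C02AC01,
C02CA01,
C02CA04,
G04CA03,
C03AA03,
C07AB02,
C07AB03,
C08CA01,
C08CA05,
C08DA01,
A03FA01,
A03BA01,
A10BB07,
A10BG03,
B01AC04,
B01AC06,
B01AC07,
H02AB06,
H02AB07,
J01MA02,
J01MA12,
N02AA01,
N02BE01,
N05AA01,
N05AA02,
N05AD01,
N05AH03,
R06AA02,
R06AB04,
N05BA01,N05BA
N05BA02,N05BA
N05BA06,N05BA
N05BA12,N05BA
N06AA09,N06AA
N06AA10,N06AA
N06AB03,N06AB
N06AB04,N06AB
N06AB05,N06AB
M01AB01,M01A
M01AB05,M01A
M01AE01,M01A
M01AE02,M01A
M01AH01,M01A
C03AA03,C03A
C07AB02,C07
C07AB03,C07
C08CA01,C08CA
C08CA05,C08CA
C08DA01,C08D
H02AB06,H02AB
H02AB07,H02AB
J01MA02,J01MA
J01MA12,J01MA
N02AA01,N02A
C02AB01,C02AB
C02CA01,C02CA
C02CA04,C02CA
N05AA01,N05A
N05AA02,N05A
N05AD01,N05A
N05AH03,N05A
N05CD02,N05C
N05CF01,N05C
N05CF02,N05C
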