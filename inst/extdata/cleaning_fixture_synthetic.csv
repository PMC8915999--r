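person_id,sex,birth_date,death_date,birth_place,death_place
P01,male,1700-03-12,1760-05-20,Bergheim,Bergheim
P02,male,1700-03-12,1760-05-20,BERGHEIM,Celle
P03,male,1710-01-01,1770-02-02,Celle,Celle
P04,male,1710-01-01,1770-02-02,célle,Bergheim
P05,male,1705-06-01,1808-07-01,Dornstadt,Dornstadt
P06,male,1850-04-04,1920-06-06,Eichberg,Eichberg
P07,male,1720-02-02,1790-03-03,Falkenau,Falkenau
P08,male,1730-05-05,1800-06-06,Bergheim,Celle
P09,male,1740-07-07,1805-08-08,Celle,Dornstadt
P10,male,1750-09-09,1810-10-10,Dornstadt,Eichberg
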