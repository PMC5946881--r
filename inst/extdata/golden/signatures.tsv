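context	SIG1	SIG2
A[C>A]A	0.0468665995313340	0.04229247915415042247
A[C>A]C	0.0207760497922395	0.00197614996047700085
A[C>A]G	0.0141910498580895	0.00063266998734660029
A[C>A]T	0.0042548299574517	0.04444411911111761926
C[C>A]A	0.0576481894235181	0.00206958995860820122
C[C>A]C	0.0048133799518662	0.00095856998082860046
C[C>A]G	0.0420307395796926	0.00073116998537660035
C[C>A]T	0.0024990999750090	0.00001491999970160001
G[C>A]A	0.0208709097912909	0.00146260997074780085
G[C>A]C	0.0024546499754535	0.00000105999997880000
G[C>A]G	0.0000000000000000	0.03426126931477462001
G[C>A]T	0.0000000000000000	0.00010797999784040006
T[C>A]A	0.0431329995686700	0.00371075992578480179
T[C>A]C	0.0022790099772099	0.05350773892984522773
T[C>A]G	0.0035015399649846	0.03997816920043661959
T[C>A]T	0.0014796199852038	0.00069591998608160041
A[C>G]A	0.0026803299731967	0.00101077997978440059
A[C>G]C	0.0000011499999885	0.00002366999952660001
A[C>G]G	0.0157048698429513	0.06500255869994883695
A[C>G]T	0.0006547899934521	0.00002688999946220001
C[C>G]A	0.0155761898442381	0.00356666992866660213
C[C>G]C	0.0002248899977511	0.00063506998729860023
C[C>G]G	0.0004982699950173	0.02265533954689321131
C[C>G]T	0.0000829599991704	0.06251424874971502066
G[C>G]A	0.0191996298080037	0.00001243999975120001
G[C>G]C	0.0000000000000000	0.00032687999346240015
G[C>G]G	0.0001224999987750	0.00411642991767140198
G[C>G]T	0.0133894698661053	0.00000806999983860001
T[C>G]A	0.0085147199148528	0.00477952990440940178
T[C>G]C	0.0011019999889800	0.00052757998944840030
T[C>G]G	0.0000000000000000	0.00184753996304920097
T[C>G]T	0.0063049599369504	0.00008428999831420004
A[C>T]A	0.0003543199964568	0.01911490961770180921
A[C>T]C	0.0803050291969497	0.00347624993047500200
A[C>T]G	0.0000000000000000	0.00302568993948620175
A[C>T]T	0.0072623399273766	0.04212839915743202268
C[C>T]A	0.0018349399816506	0.00233690995326180139
C[C>T]C	0.0308007196919928	0.00080615998387680043
C[C>T]G	0.0029625599703744	0.01138013977239720614
C[C>T]T	0.0098976199010238	0.01101467977970640652
G[C>T]A	0.0026023899739761	0.00086112998277740045
G[C>T]C	0.0593709394062906	0.00000935999981280000
G[C>T]G	0.0000410099995899	0.00000713999985720000
G[C>T]T	0.0119270198807298	0.00017031999659360009
T[C>T]A	0.0000128399998716	0.02691863946162721330
T[C>T]C	0.0293739297062607	0.00000000000000000000
T[C>T]G	0.0644299493557005	0.00340636993187260189
T[C>T]T	0.0001011099989889	0.03290324934193501749
A[T>A]A	0.0013458999865410	0.01977764960444701112
A[T>A]C	0.0025907199740928	0.00005197999896040003
A[T>A]G	0.0246997697530023	0.00042625999147480022
A[T>A]T	0.0000004399999956	0.00000184999996300000
C[T>A]A	0.0002560499974395	0.00407719991845600146
C[T>A]C	0.0001879899981201	0.01762377964752440823
C[T>A]G	0.0002118299978817	0.00011028999779420006
C[T>A]T	0.0029924099700759	0.00005782999884340003
G[T>A]A	0.0049951999500480	0.00497857990042840232
G[T>A]C	0.0100452998995470	0.00003299999934000002
G[T>A]G	0.0006396399936036	0.03184549936309001572
G[T>A]T	0.0009054499909455	0.00008023999839520005
T[T>A]A	0.0255899297441007	0.00032974999340500019
T[T>A]C	0.0000625799993742	0.00494699990106000232
T[T>A]G	0.0000032499999675	0.00008725999825480004
T[T>A]T	0.0000393399996066	0.00134378997312420076
A[T>C]A	0.0038091399619086	0.01047481979050360508
A[T>C]C	0.0037956299620437	0.00000045999999080000
A[T>C]G	0.0074734399252656	0.02634881947302361235
A[T>C]T	0.0015243399847566	0.00253520994929580133
C[T>C]A	0.0017954199820458	0.00000000000000000000
C[T>C]C	0.0012072199879278	0.00513181989736360197
C[T>C]G	0.0011242499887575	0.00493736990125260254
C[T>C]T	0.0000023699999763	0.00648878987022420348
G[T>C]A	0.0000000799999992	0.01144657977106840543
G[T>C]C	0.0032288999677110	0.03252344934953101813
G[T>C]G	0.0084039999159600	0.01226676975466460540
G[T>C]T	0.0003239199967608	0.00002567999948640002
T[T>C]A	0.0050533699494663	0.03655677926886441442
T[T>C]C	0.0001022599989774	0.02055742958885141067
T[T>C]G	0.0069678299303217	0.00000179999996400000
T[T>C]T	0.0272187697278123	0.00066931998661360042
A[T>G]A	0.0116323898836761	0.01599926968001460711
A[T>G]C	0.0000537099994629	0.00491107990177840244
A[T>G]G	0.0000730699992693	0.00977314980453700480
A[T>G]T	0.0385617496143825	0.11399257772014845247
C[T>G]A	0.0257250797427492	0.00023007999539840010
C[T>G]C	0.0015287899847121	0.00000005999999880000
C[T>G]G	0.0028009599719904	0.00041105999177880022
C[T>G]T	0.0000026299999737	0.00023650999526980012
G[T>G]A	0.1115073488849265	0.00310108993797820164
G[T>G]C	0.0001597499984025	0.00095464998090700050
G[T>G]G	0.0012275699877243	0.00273234994535300141
G[T>G]T	0.0014651599853484	0.00000231999995360000
T[T>G]A	0.0000930499990695	0.01899710962005781226
T[T>G]C	0.0051160899488391	0.00485166990296660196
T[T>G]G	0.0012894699871053	0.01252475974950480533
T[T>G]T	0.0000343299996567	0.00400269991994600151
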