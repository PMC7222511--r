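time,0,5,10,20,40,80,160,320
0,0.164362358067,0.0150341460657,0.0514609921001,0.0411198170524,0.102109326808,-0.00882657748591,0.0195002212074,0.072101969767
0.05,-0.00983858411112,0.0476196360442,0.0530326356174,0.128090573544,0.105416164462,0.130601235842,0.199946260376,0.23234273344
0.1,0.0152853744782,0.00817797372782,0.0557255064171,0.209851304501,0.208807128036,0.29141383025,0.266135491284,0.479490290595
0.15,0.0293853524432,0.066042434604,0.102385766721,0.200003740915,0.298128483013,0.312990345297,0.55157843428,0.587743727142
0.2,0.00146633294403,0.0773273442988,0.123230831257,0.217755151364,0.350997811331,0.555382743399,0.59104936618,0.893608439993
0.25,0.00263600273859,0.176713397529,0.147820635154,0.184053144905,0.310257596536,0.605258432236,0.66985582138,0.948629450828
0.3,0.0874069670145,0.150504142826,0.0962265241548,0.349658519344,0.35993418854,0.634074079614,0.905063024207,1.19179988316
0.35,0.0441522387056,0.137701371323,0.237308623644,0.310231735323,0.571912418864,0.792401803427,1.11223438025,1.28940670766
0.4,0.0576328813141,0.190932544007,0.312111888132,0.421645456322,0.677441636568,0.907400005846,1.25974494094,1.57385646304
0.45,0.159498905366,0.142919115564,0.220381931138,0.465387880509,0.624531296496,1.0014283284,1.40215835766,1.75083887696
0.5,0.0678493115165,0.167323613955,0.305887390884,0.481477774658,0.790522925168,1.23139780371,1.55303282159,1.90743745133
0.55,0.185837589157,0.197689007435,0.308995956311,0.560714604337,0.843009631433,1.26016260059,1.82673878816,2.0349420855
0.6,0.164072596299,0.276287428197,0.361693708651,0.50695847087,0.936981892912,1.38256321702,1.89109225205,2.30129583119
0.65,0.0662010270069,0.238687917925,0.312832734467,0.607842820565,1.0370870884,1.43542473827,2.0529395553,2.55016489391
0.7,0.14480335334,0.238098025144,0.419515086622,0.672075444636,1.04844027647,1.5748984158,2.16020683212,2.7002253182
0.75,0.0733840255661,0.147171896401,0.308669899044,0.680392464331,1.08126542735,1.69719698514,2.27377909176,2.90682975319
0.8,0.00530996384573,0.252970730538,0.385772490931,0.757836080303,1.29083819978,1.75330874043,2.64173237744,3.07473705875
0.85,0.0346335850231,0.256824572268,0.422108045419,0.674870802655,1.36749593721,1.97414418231,2.70949633907,3.2633263328
0.9,0.0497588788866,0.214970330927,0.477511974829,0.744615547381,1.37772168521,2.05970021697,2.85586816345,3.41596932386
0.95,0.099408207475,0.275198981681,0.502807835607,0.83695766748,1.38118122545,2.1176523053,2.98625964483,3.75104451585
1,0.0919875179812,0.2907269039,0.491290498908,0.879327071891,1.48412429639,2.31712629118,3.08461341446,3.84139327748
1.05,0.0852670915453,0.321315671072,0.458319987169,0.933284499223,1.50267433008,2.36360548136,3.27025735485,3.99532963758
1.1,0.115298236041,0.340709294512,0.55420969059,0.945712431071,1.65220593345,2.43403777734,3.3756692446,4.28946650662
1.15,-0.0193998108296,0.332728545509,0.480269941649,0.944907211597,1.6902594751,2.56271846457,3.64029757781,4.47244504835
1.2,0.113645843213,0.383527988962,0.631673447767,1.05363850935,1.64710491532,2.59704991705,3.76600739479,4.67646259015
1.25,0.0592096385618,0.377782923099,0.654869976457,1.08628335867,1.77270778695,2.8494826453,3.89417685528,4.89222909979
1.3,0.087613994787,0.408232966686,0.667271180109,1.05420907018,1.77982856497,2.88409837239,4.02111044107,4.85903734109
1.35,0.0795872526231,0.424801936311,0.652777834946,1.13109696313,2.00592652243,3.01934967745,4.12859184708,5.21594242864
1.4,0.000847370211449,0.407981876218,0.646926266743,1.24345283477,2.00042545042,3.11431351847,4.34248908772,5.43164770584
1.45,0.0361968022444,0.405739512881,0.712605641325,1.1828891456,2.0284284374,3.31213010692,4.61056483085,5.58204927764
1.5,0.00645744887157,0.349110089776,0.743287306863,1.25741672105,2.14686008588,3.27090874024,4.68575327032,5.69255141924
1.55,0.0859355276542,0.37556760569,0.762942363933,1.34122838787,2.23848199718,3.45222747972,4.82875529075,5.92386112433
1.6,0.0555326438885,0.374095143923,0.709191621333,1.30682172629,2.24508688308,3.56267363933,5.01449337273,6.05802758533
1.65,0.0460766616014,0.346508310683,0.852088651433,1.30649007449,2.35485051361,3.66968802644,5.15824788744,6.26635430849
1.7,0.0289754770329,0.373223016276,0.734003275929,1.48437052417,2.39702260674,3.75627150917,5.35302400109,6.4775882462
1.75,0.0218937061857,0.406068784475,0.872416895296,1.5256979452,2.52657840319,3.86582042505,5.43494985896,6.81313043904
1.8,0.0998756722378,0.433621027853,0.887491943809,1.50317072813,2.66375145383,4.00190320525,5.47747210808,6.89387259179
1.85,-0.00525650294066,0.469336485632,0.874634283576,1.56006943931,2.67382898122,4.05347850119,5.6734832842,7.11734119011
1.9,0.0428856084613,0.604521691822,0.802702489708,1.58651040222,2.69748886461,4.28737524618,5.86163454351,7.23775634337
1.95,0.0657497452444,0.511421789452,0.979909367211,1.62107881867,2.79670597726,4.29924205891,5.98068426794,7.46546074702
2,0.110927526725,0.505385501646,0.956769768578,1.69673915583,2.89534809527,4.52351899624,6.16537972388,7.61764379211
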