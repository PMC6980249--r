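start	rate
0	9.8e-09
25000	6.984e-09
50000	8.638e-09
75000	4.202e-09
100000	1.223e-09
125000	1.548e-09
150000	6.158e-09
175000	1.579e-09
200000	3.024e-08
225000	4.133e-08
250000	9.688e-10
275000	3.724e-09
300000	4.813e-09
325000	1.057e-08
350000	5.51e-09
375000	1.024e-08
400000	5.947e-08
425000	7.532e-09
450000	3.108e-09
475000	1.297e-09
500000	2.266e-08
525000	1.718e-09
550000	3.136e-09
575000	1.594e-09
600000	2.228e-09
625000	3.187e-08
650000	1.814e-08
675000	5.919e-10
700000	3.251e-09
725000	3.339e-08
750000	1.444e-08
775000	5.512e-09
800000	3.54e-08
825000	5.138e-09
850000	2.069e-09
875000	1.333e-09
900000	2.059e-09
925000	3.728e-08
950000	9.315e-09
975000	1.199e-08
1000000	8.363e-10
1025000	5.091e-09
1050000	7.388e-09
1075000	3.543e-09
1100000	2.382e-08
1125000	7.338e-10
1150000	5.656e-09
1175000	6.004e-09
1200000	1.359e-09
1225000	4.942e-09
1250000	3.404e-09
1275000	3.356e-08
1300000	1.761e-09
1325000	1.858e-09
1350000	1.759e-08
1375000	2.627e-09
1400000	7.759e-09
1425000	9.418e-10
1450000	1.369e-08
1475000	5.542e-09
1500000	6.537e-09
1525000	6.247e-10
1550000	5.226e-09
1575000	4.754e-09
1600000	1.29e-09
1625000	1.551e-08
1650000	1.504e-08
1675000	3.709e-09
1700000	1.42e-09
1725000	1.062e-08
1750000	1.338e-08
1775000	3.441e-09
1800000	1.751e-09
1825000	6.462e-10
1850000	4.554e-09
1875000	1.319e-08
1900000	3.661e-09
1925000	3.302e-09
1950000	2.975e-09
1975000	6.709e-09
2000000	4.129e-09
2025000	1.458e-08
2050000	3.38e-09
2075000	2.689e-08
2100000	1.949e-08
2125000	3.375e-09
2150000	3.824e-09
2175000	3.083e-09
2200000	6.42e-09
2225000	2.486e-09
2250000	2.562e-09
2275000	8.506e-08
2300000	3.612e-09
2325000	3.584e-08
2350000	6.995e-09
2375000	2.752e-09
2400000	5.133e-09
2425000	1.3e-09
2450000	3.254e-09
2475000	2.607e-09
2500000	2.083e-09
2525000	1.23e-09
2550000	2.022e-09
2575000	4.41e-09
2600000	1.197e-09
2625000	1.511e-08
2650000	1.127e-08
2675000	6.057e-09
2700000	1.79e-08
2725000	1.716e-08
2750000	8.747e-09
2775000	1.819e-09
2800000	4.009e-09
2825000	4.055e-09
2850000	6.271e-09
2875000	2.469e-08
2900000	1.004e-09
2925000	1.785e-09
2950000	8.016e-08
2975000	5.068e-09
3000000	1.884e-08
3025000	1.619e-09
3050000	4.957e-08
3075000	4.104e-09
3100000	2.041e-09
3125000	7.892e-09
3150000	7.618e-09
3175000	2.22e-08
3200000	1.37e-08
3225000	8.751e-09
3250000	3.965e-09
3275000	9.466e-09
3300000	8.43e-10
3325000	1.334e-08
3350000	2.368e-09
3375000	1.176e-08
3400000	4.305e-09
3425000	1.525e-09
3450000	7.216e-08
3475000	5.508e-09
3500000	1.793e-09
3525000	7.064e-09
3550000	1.458e-09
3575000	4.48e-09
3600000	2.702e-09
3625000	2.175e-09
3650000	3.624e-08
3675000	3.695e-09
3700000	2.107e-08
3725000	2.771e-09
3750000	2.752e-09
3775000	1.195e-09
3800000	3.774e-09
3825000	3.08e-09
3850000	3.594e-09
3875000	4.971e-09
3900000	3.295e-09
3925000	6.453e-09
3950000	2.626e-08
3975000	1.079e-08
4000000	3.242e-09
4025000	1.716e-08
4050000	2.262e-09
4075000	1.543e-08
4100000	7.347e-10
4125000	7.478e-09
4150000	2.121e-09
4175000	4.096e-09
4200000	9.902e-09
4225000	4.034e-09
4250000	1.59e-09
4275000	5.258e-09
4300000	3.573e-09
4325000	1.338e-08
4350000	8.219e-09
4375000	1.676e-09
4400000	1.016e-08
4425000	2.238e-09
4450000	4.764e-08
4475000	2.737e-09
4500000	8.545e-09
4525000	2.392e-08
4550000	3.168e-08
4575000	1.677e-08
4600000	5.244e-08
4625000	4.222e-09
4650000	1.407e-08
4675000	3.056e-09
4700000	1.756e-09
4725000	7.763e-09
4750000	1.595e-09
4775000	1.875e-09
4800000	8.566e-09
4825000	5.613e-09
4850000	4.455e-10
4875000	1.222e-09
4900000	4.887e-08
4925000	5.909e-09
4950000	3.629e-09
4975000	2.59e-09
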